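---
title: "Methods: permutation tests for no-data zones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation tests for no-data zones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zoneperm)
```

## The statistic

A scatterplot corner with no observations is delineated by a boundary line
built from the data's Pareto-extreme points and closed through the corner
of the data bounding box.  The statistic is the zone's relative areal
extent

$$Q = \frac{\text{area of the zone polygon}}{\text{area of the bounding box}},
\qquad 0 \le Q < 1 .$$

Significance comes from a permutation null: the $x$ and $y$ coordinate
vectors are each reordered at random — sampling without replacement — which
destroys any $x$–$y$ dependence while preserving both marginal
distributions (and therefore the bounding box).  With $n_\mathrm{perm}$
permuted areas $Q_\mathrm{perm}$, mean $\bar{Q}_\mathrm{perm}$ and sample
standard deviation $s$, the one-tailed Z-test is

$$Z = \frac{Q_\mathrm{obs} - \bar{Q}_\mathrm{perm}}{s},
\qquad p = P\!\left(\mathcal{N}(0,1) > Z\right).$$

Only an *excess* of empty area is tested: negative $Z$ gives $p > 0.5$ and
is never called significant.  The test assumes independent observations
and exchangeability of the pairing under the null; it makes no assumption
about the form of the $x$–$y$ relationship, homoscedasticity, or residual
distributions.  Its flip side is outlier sensitivity: a single extreme
point stretches the bounding box and can reshape the boundary, so the
statistic is *potentially extremely* sensitive to outliers — more so than
regression-based envelope methods.

Both coordinate vectors are shuffled even though permuting one alone
induces the same null law; this mirrors the procedure as usually printed
and costs nothing.

## The boundary construction

Written for the canonical upper-left corner (zone A); zones B, C, D are
mapped onto it by sign reflections (negate $x$, $y$, or both) and back
again, so all four corners share one algorithm and one set of tests.

1. Start at the minimum-$x$ point.
2. Among points with strictly greater $x$ **and** strictly greater $y$,
   connect to the one closest in the $x$ direction.
3. Repeat from the new point until no candidate remains.
4. Close the polyline through the corner point
   $(x_{\min},\, y_{\max})$ of the bounding box.

The vertex sequence is the Pareto front for (minimise $x$, maximise $y$);
the implementation sorts once by $(x\ \uparrow,\, y\ \downarrow)$ and takes
the strict running maximum of $y$, which is algebraically identical to the
step-by-step walk (the test suite checks this against a literal walk on
hundreds of scatters, including tied and duplicated coordinates).  The
polygon area is the absolute shoelace sum halved, cross-checked in the
tests against trapezoidal quadrature of $(y_{\max} - \text{polyline}(x))$.

Numerical and degenerate-input choices, each with its rationale:

* **"Corner of the plot" = corner of the data bounding box**, not of any
  displayed axis limits.  Permutations preserve the data box, making $Q$
  comparable across permutations; axis limits are a presentation choice the
  statistic should not depend on.  Results will differ from a reading based
  on wider axis limits.
* **Strict dominance** ("greater than" read strictly in both coordinates)
  prevents zero-length segments and infinite loops on ties.
* **Tie-breaks favour the zone**: among points tied at the relevant $x$,
  the one with maximum $y$ (canonical orientation) is chosen — any lower
  choice would strand a data point inside the "no-data" polygon.
* **Duplicate points are harmless**; at most one copy is ever selected.
* **Degenerate bounding box** (all $x$ equal or all $y$ equal) is a hard
  error, not $Q = 0$: a test of 2-D areal extent is meaningless without
  2-D spread.
* **Ring closure** removes consecutive duplicate vertices; fewer than three
  distinct vertices (boundary starting at the corner itself) is the
  legitimate $Q = 0$ case.
* $s$ uses the $n-1$ denominator, conventional for an estimated null.
* **Zero-spread null** ($s = 0$): $Z = 0$ if $Q_\mathrm{obs}$ equals the
  null mean; otherwise $Z$ is signed infinity with a warning and $p$ is
  reported as the conservative permutation bound $1/(n_\mathrm{perm}+1)$
  (or $n_\mathrm{perm}/(n_\mathrm{perm}+1)$ on the lower side).

The boundary definition is a hook, not a commitment: any deterministic
`function(points, zone)` returning a closed ring inside the bounding box
can be registered (`register_boundary_provider()`) and the permutation
machinery applies unchanged.  Quantile-regression or kernel-density
boundaries are deliberately out of scope here; only the staircase is built
in.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_perm` | 10,000 | permutations per zone; the default follows standard practice for stable tail estimates.  99–999 are adequate for exploration and are used throughout the test suite for speed. |
| `seed` | random, recorded | one user seed; each zone derives an independent substream by a fixed offset (A +0, B +1, C +2, D +3, mod $2^{31}-1$), so a zone's result is identical whether tested alone or with others. |
| `provider` | `"staircase"` | boundary definition (see above). |
| `bonferroni` | off | multiplies per-zone p-values by the number of zones tested, capped at 1.  Off by default because the per-zone p is the primary report; turn it on when screening all four corners without a prior hypothesis. |
| `zones` | A–D | which corners to test. |

Two p-values are always reported: `p_z` from the normal approximation
(the headline value) and the add-one empirical `p_emp`
$= (1 + \#\{Q_\mathrm{perm} \ge Q_\mathrm{obs}\})/(1 + n_\mathrm{perm})$,
which cannot be zero and counts ties against the observation.  The normal
approximation to $Q_\mathrm{perm}$ is just that — an approximation; it is
what allows $p \ll 1/n_\mathrm{perm}$ to be quoted, but such extreme tails
inherit the approximation error, while `p_emp` is exact but floored at
$1/(n_\mathrm{perm}+1)$.  The significance ladder used for labels is
`p ≤ 1e-10 *****`, `≤ 1e-6 ****`, `≤ 1e-4 ***`, `≤ 0.001 **`,
`≤ 0.005 *`, `> 0.05 NS`; the band $(0.005, 0.05]$ sits between the
starred and non-significant ranges, is labelled `n.s.-gap`, and the whole
ladder is configurable (`stars()`) rather than hard-coded.

`permutation_self_z()` is a diagnostic companion: each permuted boundary
is Z-tested against the other $n_\mathrm{perm}-1$, which is useful for
visualising where "typical" and "borderline significant" permuted
boundaries fall.  Leave-one-out mean and standard deviation are used —
including the value in its own reference set would bias its score.

## What the synthetic generators emulate — and what they do not

All generators live on the unit square ($Q$ is invariant to translation
and positive rescaling of either axis, so this is lossless) and use
piecewise-linear envelopes so that expected zone areas have closed forms
usable as oracles:

* `gen_independent(n, seed)`: iid uniform, independent — the null case.
* `gen_triangular(n, strength, seed)`:
  $y = u\,[(1-\text{strength}) + \text{strength}\cdot x]$,
  $u \sim U(0,1)$ — a rising constraint envelope leaving zone A empty;
  at `strength = 1` every point satisfies $y \le x$ and the expected
  zone-A extent approaches the triangle area $0.5$.
* `gen_promotion(n, strength, seed)`: the point reflection
  $(x,y) \mapsto (1-x,\,1-y)$ of the triangular scatter, so
  $y \ge \text{strength}\cdot x$ and zone D is empty by construction.
  The point reflection (rather than a single-axis mirror) is what maps
  corner A onto corner D, so the zone-D area of a promotion scatter equals
  the zone-A area of the matching triangular scatter exactly, and
  `strength = 1` gives $y \ge x$.
* `gen_humped(n, strength, asymmetry, seed)`: a piecewise-linear humped
  envelope rising from $(0, 1-\text{strength})$ to a peak at
  $(0.5 + \text{asymmetry},\, 1)$ and falling to $(1, 1-\text{strength})$
  — both upper corners depleted, more on the side away from the peak,
  emulating asymmetric constraint–promotion ("humped") field datasets that
  symmetric parabolic fits handle poorly.  The peak is clamped to
  $[10^{-8}, 1-10^{-8}]$ to keep the envelope two-sided.

Envelope compliance is exact by construction, and `strength = 0` reduces
every shape to the independent null *bitwise* (same draw order), which the
tests exploit.

These scatters are idealisations.  Real ecological data have measurement
error, censoring and rounding, heteroscedastic marginals, spatial or
phylogenetic non-independence, and outliers — none of which the generators
emulate.  Passing calibration and power checks on these shapes therefore
demonstrates that the machinery is correct and the test behaves as
designed under its own assumptions; it does not certify nominal error
rates on data whose observations are not independent, and it says nothing
about subsetting: restricting a scatter to a sub-range can flip
significance, so subsets should be chosen a priori, never searched over.

## Problem sizes used in validation

The shipped suite checks, among ~40 blocks: shoelace vs quadrature
agreement ($|\Delta Q| < 10^{-9}$) on 200 random scatters of 5–200 points;
the no-point-strictly-inside invariant on 1,000 scatters × 4 zones via an
independent crossing-number test; exact reflection symmetry on 500
scatters; type-I calibration with 400 replicates of $n = 100$ independent
points at 199 permutations (rejection rate at $\alpha = 0.05$ within the
99% binomial band, Kolmogorov–Smirnov uniformity of the p-values at the 1%
level); and power with 100 replicates of strength-1 triangular scatters
($n = 200$, 999 permutations), requiring $p_z \le 0.001$ in at least 90.
These sizes keep the full suite around a minute on one CPU while leaving
Monte-Carlo margins comfortably wide.

## Known limitations

* Extreme-point construction ⇒ extreme outlier sensitivity (by design;
  robustify upstream if needed).
* `p_z` in very deep tails leans on the normality of $Q_\mathrm{perm}$.
* Exact ties are resolved by documented conventions, not by the underlying
  theory; data rounded to very few distinct values deserve a look at the
  boundary plot before trusting $Q$.
* One zone at a time: the four zone statistics are correlated (they share
  the bounding box), and the optional Bonferroni correction is
  conservative for them.
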