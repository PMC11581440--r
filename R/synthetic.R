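#' Synthetic scatters with known no-data-zone structure
#'
#' Seeded generators on the unit square used to calibrate and power-test
#' the zone tests without external data.  Because Q is invariant under
#' translation and positive rescaling of either axis, the unit-square
#' support is lossless and makes Q values directly interpretable.
#'
#' * `gen_independent()` — x and y iid uniform(0,1), independent: the null
#'   case.  All four zone tests should reject at their nominal rate only.
#' * `gen_triangular()` — a rising constraint envelope: y = u * ((1 -
#'   strength) + strength * x) with u ~ uniform(0,1), so every point lies on
#'   or below the line from (0, 1 - strength) to (1, 1) and the upper-left
#'   zone (A) is empty above it by construction.  `strength` is the fraction
#'   of the left edge excluded; `strength = 0` reduces to the independent
#'   null, `strength = 1` gives y <= x.
#' * `gen_promotion()` — the point reflection (x, y) -> (1 - x, 1 - y) of
#'   the triangular scatter: every point satisfies y >= strength * x, so
#'   the lower-right zone (D) is empty by construction, emulating promotion
#'   of y at high x (`strength = 1` gives y >= x).  Because the reflection
#'   maps corner D onto corner A, the zone-D area of a promotion scatter
#'   equals the zone-A area of the matching triangular scatter exactly.
#' * `gen_humped()` — a piecewise-linear humped envelope rising from
#'   (0, 1 - strength) to a peak at (p, 1) and falling to (1, 1 - strength),
#'   with p = 0.5 + asymmetry; both upper corners are depleted when
#'   `strength > 0`, more so on the side away from the peak.
#'
#' Envelope compliance is exact, not statistical, so expected zone areas
#' have closed forms usable as test oracles.
#'
#' @param n number of points, at least 3.
#' @param strength envelope strength in [0, 1]; 0 reduces every shape to
#'   the independent null.
#' @param asymmetry humped shape only: horizontal shift of the peak away
#'   from x = 0.5 (clamped to keep the peak inside (0, 1)).
#' @param seed integer seed; every generator is deterministic given
#'   `(n, strength, asymmetry, seed)` and leaves the caller's RNG state
#'   untouched.
#' @return A [point_set()] of `n` points.
#' @examples
#' gen_triangular(5, strength = 1, seed = 1)
#' @name synthetic
NULL

.check_gen_args <- function(n, strength = 0) {
  if (n < 3L) stop("n must be at least 3")
  if (strength < 0 || strength > 1) stop("strength must be in [0, 1]")
}

#' @rdname synthetic
#' @export
gen_independent <- function(n, seed) {
  .check_gen_args(n)
  withr::with_seed(seed, .ps(stats::runif(n), stats::runif(n)))
}

#' @rdname synthetic
#' @export
gen_triangular <- function(n, strength, seed) {
  .check_gen_args(n, strength)
  withr::with_seed(seed, {
    x <- stats::runif(n)
    u <- stats::runif(n)
    .ps(x, u * ((1 - strength) + strength * x))
  })
}

#' @rdname synthetic
#' @export
gen_promotion <- function(n, strength, seed) {
  d <- gen_triangular(n, strength, seed)
  .ps(1 - d$x, 1 - d$y)
}

#' @rdname synthetic
#' @export
gen_humped <- function(n, strength, asymmetry = 0, seed) {
  .check_gen_args(n, strength)
  peak <- min(max(0.5 + asymmetry, 1e-8), 1 - 1e-8)
  withr::with_seed(seed, {
    x <- stats::runif(n)
    u <- stats::runif(n)
    h <- ifelse(x <= peak,
                (1 - strength) + strength * x / peak,
                (1 - strength) + strength * (1 - x) / (1 - peak))
    .ps(x, u * h)
  })
}
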