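#' Randomly re-pair the x and y coordinates
#'
#' One permutation step of the null model: the X and Y coordinate vectors
#' are each reordered at random (sampling without replacement), producing a
#' new set of x-y pairs with the same marginals — and hence the same
#' bounding box — but with any dependence between x and y destroyed.
#'
#' @param points a [point_set()].
#' @param seed optional integer; when given, the shuffle is done in a
#'   temporary seeded RNG stream, leaving the caller's RNG state untouched.
#'   When `NULL`, the current RNG stream is used (and advanced).
#' @return A `point_set` with shuffled pairing.
#' @export
shuffle_pairing <- function(points, seed = NULL) {
  p <- as_point_set(points)
  n <- nrow(p)
  if (is.null(seed))
    return(.ps(p$x[sample.int(n)], p$y[sample.int(n)]))
  withr::with_seed(seed, .ps(p$x[sample.int(n)], p$y[sample.int(n)]))
}

#' Permutation null distribution of the zone area Q
#'
#' Repeats [shuffle_pairing()] + [zone_q()] `n_perm` times (the default
#' 10,000) and records the permuted zone areas, their mean and their sample
#' standard deviation (n - 1 denominator).  Bit-for-bit reproducible given
#' `(points, zone, n_perm, seed, provider)`.
#'
#' @inheritParams zone_q
#' @param n_perm number of permutations, at least 2; default 10,000.
#' @param seed integer seed for the permutation stream; drawn at random (and
#'   recorded in the result) when `NULL`.
#' @return A list of class `null_dist`: `zone`, `q_values`, `mean`, `sd`,
#'   `n_perm`, `seed`.
#' @export
build_null <- function(points, zone = "A", n_perm = 10000L, seed = NULL,
                       provider = "staircase") {
  p <- as_point_set(points)
  zone <- .match_zone(zone)
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 2L)
    stop("n_perm must be an integer >= 2")
  if (is.null(seed))
    seed <- sample.int(.Machine$integer.max, 1L)
  pfun <- boundary_provider(provider)
  barea <- .box_area(bounding_box(p))
  n <- nrow(p)
  x <- p$x
  y <- p$y
  q <- withr::with_seed(seed,
    vapply(seq_len(n_perm), function(i) {
      perm <- .ps(x[sample.int(n)], y[sample.int(n)])
      shoelace_area(pfun(perm, zone)) / barea
    }, numeric(1)))
  s <- stats::sd(q)
  if (s == 0)
    warning("degenerate null distribution: all permuted Q values identical")
  structure(list(zone = zone, q_values = q, mean = mean(q), sd = s,
                 n_perm = n_perm, seed = as.integer(seed)),
            class = "null_dist")
}

#' @export
print.null_dist <- function(x, ...) {
  cat(sprintf("permutation null for zone %s: %d permutations (seed %d)\n",
              x$zone, x$n_perm, x$seed))
  cat(sprintf("  mean Q = %g, sd = %g\n", x$mean, x$sd))
  invisible(x)
}

#' Z statistic of an observed zone area against its permutation null
#'
#' Z = (Q_obs - mean(Q_perm)) / sd(Q_perm).  When the null has zero spread
#' the statistic is degenerate: Z = 0 if the observed value equals the null
#' mean, otherwise signed infinity with a warning (callers report p as the
#' empirical permutation bound in that case, see [run_zone_tests()]).
#'
#' @param q_obs observed relative zone area.
#' @param null a [build_null()] result.
#' @return The Z score (possibly `Inf`/`-Inf` in the degenerate case).
#' @export
z_statistic <- function(q_obs, null) {
  if (null$sd > 0)
    return((q_obs - null$mean) / null$sd)
  if (q_obs == null$mean)
    return(0)
  warning("degenerate null (sd = 0) with Q_obs != mean: Z is infinite")
  sign(q_obs - null$mean) * Inf
}

#' One-tailed p-value from a Z score
#'
#' Upper-tail standard-normal probability: the probability of a zone area at
#' least as far above the null mean as observed.  Negative Z gives p > 0.5
#' and is never significant — only excess no-data area is tested.
#'
#' @param z Z score.
#' @return Upper-tail probability, strictly decreasing in `z`.
#' @export
p_value <- function(z) stats::pnorm(z, lower.tail = FALSE)

#' Empirical (exact-permutation) p-value
#'
#' Add-one permutation estimate `(1 + #\{Q_perm >= Q_obs\}) / (1 + n_perm)`,
#' the conventional exact alternative to the normal approximation; it can
#' never be 0 and ties count against the observation.
#'
#' @inheritParams z_statistic
#' @return p in `(0, 1]`.
#' @export
empirical_p <- function(q_obs, null) {
  (1 + sum(null$q_values >= q_obs)) / (1 + null$n_perm)
}

#' Significance star labels
#'
#' Maps p-values onto the star ladder used in this package's figures:
#' p <= 1e-10 `*****`, <= 1e-6 `****`, <= 1e-4 `***`, <= 0.001 `**`,
#' <= 0.005 `*`, and p > 0.05 `NS`.  The ladder leaves (0.005, 0.05]
#' between the starred and non-significant ranges; it is labelled
#' `"n.s.-gap"` by default and the whole ladder is configurable.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param thresholds increasing upper thresholds for each label.
#' @param labels labels matching `thresholds`; the first threshold with
#'   `p <= threshold` wins.
#' @param ns_label label for p above every threshold.
#' @return Character vector of labels.
#' @examples
#' stars(c(1e-12, 9e-4, 0.2))
#' @export
stars <- function(p,
                  thresholds = c(1e-10, 1e-6, 1e-4, 1e-3, 5e-3, 5e-2),
                  labels = c("*****", "****", "***", "**", "*", "n.s.-gap"),
                  ns_label = "NS") {
  stopifnot(length(thresholds) == length(labels),
            !is.unsorted(thresholds))
  vapply(p, function(pi) {
    i <- which(pi <= thresholds)[1L]
    if (is.na(i)) ns_label else labels[i]
  }, character(1))
}

.zone_stream_seed <- function(seed, zone) {
  offset <- c(A = 0, B = 1, C = 2, D = 3)[[zone]]
  as.integer((as.double(seed) + offset) %% 2147483647)
}

#' Permutation tests of no-data zones
#'
#' Runs the full procedure for each requested zone: measure the observed
#' zone area Q, build a permutation null of `n_perm` re-pairings of the x
#' and y coordinates, and compare the observed Q to the null mean with a
#' one-tailed Z-test.  The empirical permutation p-value is reported
#' alongside the normal-approximation `p_z`, which remains the headline
#' p-value.
#'
#' Each zone uses an independent permutation stream derived from `seed` by a
#' fixed per-zone offset, so a zone's result is identical whether it is
#' tested alone or together with other zones.  No multiple-testing
#' adjustment is applied unless `bonferroni = TRUE`, which multiplies the
#' per-zone p-values by the number of zones tested (capped at 1).
#'
#' If the null distribution is degenerate (sd = 0) and the observed Q
#' differs from the null mean, `Z` is infinite and `p_z` is reported as the
#' conservative empirical bound `1/(n_perm + 1)` (upper side) or
#' `n_perm/(n_perm + 1)` (lower side).
#'
#' @inheritParams build_null
#' @param zones character vector of zone labels, any of `"A"`, `"B"`,
#'   `"C"`, `"D"`, or `"all"`.
#' @param bonferroni logical; Bonferroni-adjust p-values across the tested
#'   zones.
#' @return A data frame of class `zone_test_result`, one row per zone, with
#'   columns `zone`, `n_points`, `Q_obs`, `mean_null`, `sd_null`, `Z`,
#'   `p_z`, `p_emp`, `stars`, `n_perm`, `seed`.
#' @examples
#' pts <- gen_triangular(100, strength = 1, seed = 7)
#' run_zone_tests(pts, zones = "A", n_perm = 99, seed = 1)
#' @export
run_zone_tests <- function(points, zones = c("A", "B", "C", "D"),
                           n_perm = 10000L, seed = NULL,
                           provider = "staircase", bonferroni = FALSE) {
  p <- as_point_set(points)
  if (nrow(p) < 3L)
    stop(errorCondition("insufficient data: at least 3 points are required",
                        class = c("zoneperm_insufficient_error",
                                  "error", "condition")))
  if (length(zones) == 1L && tolower(zones) == "all")
    zones <- .zone_labels
  zones <- unique(vapply(zones, .match_zone, character(1), USE.NAMES = FALSE))
  if (length(zones) == 0L)
    stop("no zones requested")
  if (is.null(seed))
    seed <- sample.int(.Machine$integer.max, 1L)
  seed <- as.integer(seed)
  n_perm <- as.integer(n_perm)

  rows <- lapply(zones, function(z) {
    null <- build_null(p, z, n_perm = n_perm,
                       seed = .zone_stream_seed(seed, z),
                       provider = provider)
    q_obs <- zone_q(p, z, provider = provider)$Q
    zstat <- z_statistic(q_obs, null)
    p_z <- if (is.finite(zstat)) {
      p_value(zstat)
    } else if (zstat > 0) {
      1 / (n_perm + 1)
    } else {
      n_perm / (n_perm + 1)
    }
    data.frame(zone = z, n_points = nrow(p), Q_obs = q_obs,
               mean_null = null$mean, sd_null = null$sd, Z = zstat,
               p_z = p_z, p_emp = empirical_p(q_obs, null),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (bonferroni) {
    k <- length(zones)
    res$p_z <- pmin(1, res$p_z * k)
    res$p_emp <- pmin(1, res$p_emp * k)
  }
  res$stars <- stars(res$p_z)
  res$n_perm <- n_perm
  res$seed <- seed
  class(res) <- c("zone_test_result", "data.frame")
  res
}

#' @export
print.zone_test_result <- function(x, digits = 4, ...) {
  cat(sprintf("no-data zone permutation tests (%d permutations, seed %d)\n",
              x$n_perm[1L], x$seed[1L]))
  df <- as.data.frame(x)
  df$Q_obs <- signif(df$Q_obs, digits)
  df$mean_null <- signif(df$mean_null, digits)
  df$sd_null <- signif(df$sd_null, digits)
  df$Z <- signif(df$Z, digits)
  df$p_z <- signif(df$p_z, 3)
  df$p_emp <- signif(df$p_emp, 3)
  print(df[, c("zone", "n_points", "Q_obs", "mean_null", "sd_null",
               "Z", "p_z", "p_emp", "stars")], row.names = FALSE)
  invisible(x)
}

#' Leave-one-out Z scores within a permutation null
#'
#' Diagnostic companion to the main test: each permuted boundary line can
#' itself be Z-tested against the remaining `n_perm - 1` lines, showing
#' where "typical" and "borderline-significant" permuted boundaries fall.
#' For permutation i, `Z_i = (q_i - mean(q[-i])) / sd(q[-i])` with the
#' sample standard deviation of the others.
#'
#' @param null a [build_null()] result with at least 3 permutations.
#' @return Numeric vector of leave-one-out Z scores (all 0 when the null
#'   has zero spread; infinite entries, with a warning, when removing one
#'   value leaves a zero-spread remainder).
#' @export
permutation_self_z <- function(null) {
  q <- null$q_values
  n <- length(q)
  if (n < 3L)
    stop("need at least 3 permutations for leave-one-out Z scores")
  qc <- q - mean(q)                      # shift-invariant, better conditioned
  s_all <- sum(qc)
  ss_all <- sum(qc^2)
  m <- (s_all - qc) / (n - 1)
  v <- (ss_all - qc^2 - (n - 1) * m^2) / (n - 2)
  v[v < 0] <- 0
  s <- sqrt(v)
  z <- (qc - m) / s
  zero_spread <- s == 0
  z[zero_spread & qc == m] <- 0
  bad <- zero_spread & qc != m
  if (any(bad)) {
    warning("degenerate leave-one-out null: infinite Z for ",
            sum(bad), " permutation(s)")
    z[bad] <- sign(qc[bad] - m[bad]) * Inf
  }
  z
}
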