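# Independent oracles used to cross-check the package implementation.
# Everything here is written from first principles (literal procedure
# walks, quadrature, crossing-number geometry) and shares no code with R/.

# deterministic random point set for case index i; mixes distributions and
# (for even i) 1-decimal rounding to induce exact ties and duplicates
oracle_point_set <- function(i, n_min = 5, n_max = 200) {
  withr::with_seed(100000 + i, {
    n <- sample(n_min:n_max, 1)
    x <- switch(1 + i %% 3,
                stats::runif(n),
                stats::rnorm(n),
                stats::rexp(n))
    y <- switch(1 + (i %/% 3) %% 3,
                stats::runif(n),
                stats::rnorm(n),
                stats::rexp(n))
    if (i %% 2 == 0) {
      x <- round(x, 1)
      y <- round(y, 1)
      # rounding must not collapse the bounding box
      if (length(unique(x)) < 2 || length(unique(y)) < 2) {
        x <- x + seq_len(n) * 1e-6
        y <- y + seq_len(n) * 1e-6
      }
    }
    point_set(x, y)
  })
}

# literal walk of the boundary procedure (canonical upper-left form):
# start at min x (tie: max y); repeatedly take, among points with strictly
# greater x and strictly greater y, the smallest x (tie: max y)
oracle_staircase <- function(x, y) {
  pick <- function(xs, ys) {
    cand <- which(xs == min(xs))
    cand[which.max(ys[cand])]
  }
  i <- pick(x, y)
  seq_x <- x[i]
  seq_y <- y[i]
  repeat {
    ok <- x > seq_x[length(seq_x)] & y > seq_y[length(seq_y)]
    if (!any(ok)) break
    j <- which(ok)[pick(x[ok], y[ok])]
    seq_x <- c(seq_x, x[j])
    seq_y <- c(seq_y, y[j])
  }
  cbind(x = seq_x, y = seq_y)
}

# quadrature oracle for the canonical zone-A relative area: trapezoidal
# integration of (ymax - polyline) over [x_first, x_last] plus the
# rectangular strip left of x_first
oracle_zone_a_q <- function(points) {
  p <- as.data.frame(points)
  v <- oracle_staircase(p$x, p$y)
  xmin <- min(p$x); xmax <- max(p$x)
  ymin <- min(p$y); ymax <- max(p$y)
  k <- nrow(v)
  area <- (v[1, 1] - xmin) * (ymax - v[1, 2])
  if (k > 1) {
    dx <- diff(v[, 1])
    mid <- (v[-k, 2] + v[-1, 2]) / 2
    area <- area + sum(dx * (ymax - mid))
  }
  area / ((xmax - xmin) * (ymax - ymin))
}

# crossing-number point-in-polygon: TRUE only if strictly inside (points on
# or numerically indistinguishable from the boundary count as outside)
oracle_point_in_ring <- function(px, py, ring, eps = 1e-12) {
  if (nrow(ring) < 3) return(FALSE)
  x1 <- ring[, 1]; y1 <- ring[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  cross2 <- (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1)
  len2 <- (x2 - x1)^2 + (y2 - y1)^2
  on_seg <- cross2^2 <= eps * pmax(len2, 1) &
    px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
    py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
  if (any(on_seg)) return(FALSE)
  straddle <- (y1 > py) != (y2 > py)
  if (!any(straddle)) return(FALSE)
  xint <- x1[straddle] +
    (py - y1[straddle]) * (x2[straddle] - x1[straddle]) /
    (y2[straddle] - y1[straddle])
  sum(px < xint) %% 2 == 1
}

# leave-one-out Z scores by direct looping
oracle_loo_z <- function(q) {
  vapply(seq_along(q), function(i) {
    rest <- q[-i]
    (q[i] - mean(rest)) / stats::sd(rest)
  }, numeric(1))
}
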