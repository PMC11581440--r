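#' Plot a zone boundary over its scatter
#'
#' Draws the scatter, shades the no-data zone polygon, and marks the
#' boundary vertices and the zone's corner point.
#'
#' @param x a [zone_boundary()] object.
#' @param main plot title; default describes the zone and Q.
#' @param zone_col fill colour for the zone polygon.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.zone_boundary <- function(x, main = NULL,
                               zone_col = grDevices::adjustcolor("firebrick", 0.25),
                               ...) {
  if (is.null(main))
    main <- sprintf("Zone %s: Q = %.3f", x$zone, x$Q)
  graphics::plot(x$points$x, x$points$y, pch = 16,
                 col = grDevices::adjustcolor("grey25", 0.6),
                 xlab = "x", ylab = "y", main = main, ...)
  if (nrow(x$ring) >= 3L)
    graphics::polygon(x$ring[, 1L], x$ring[, 2L], col = zone_col,
                      border = "firebrick", lwd = 2)
  graphics::points(x$vertices[, 1L], x$vertices[, 2L], pch = 21,
                   bg = "firebrick", col = "white", cex = 1.2)
  graphics::points(x$corner[["x"]], x$corner[["y"]], pch = 4, lwd = 2,
                   col = "firebrick")
  invisible(x)
}

#' Plot a permutation null distribution
#'
#' Histogram of the permuted zone areas with the observed Q marked, the
#' usual visual companion of the Z-test.
#'
#' @param x a [build_null()] object.
#' @param q_obs optional observed Q to mark with a vertical line.
#' @param main plot title.
#' @param ... further arguments passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.null_dist <- function(x, q_obs = NULL, main = NULL, ...) {
  if (is.null(main))
    main <- sprintf("Permutation null, zone %s (%d permutations)",
                    x$zone, x$n_perm)
  xlim <- range(c(x$q_values, q_obs))
  graphics::hist(x$q_values, breaks = "FD", col = "grey80",
                 border = "grey50", xlab = expression(Q[perm]),
                 main = main, xlim = xlim, ...)
  if (!is.null(q_obs)) {
    graphics::abline(v = q_obs, col = "firebrick", lwd = 2)
    graphics::mtext(sprintf("Q_obs = %.3f", q_obs), col = "firebrick",
                    side = 3, adj = 1, cex = 0.8)
  }
  invisible(x)
}
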