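#' Bounding box of a point set
#'
#' The "full dataset" area against which a no-data zone is measured is the
#' axis-aligned bounding box of the observed data (componentwise min/max of
#' x and y).  Permutations of the pairing preserve both marginals and hence
#' the box, which keeps the relative area Q comparable across permutations.
#'
#' @param points a [point_set()] or coercible object.
#' @return A list of class `bounding_box` with elements `xmin`, `xmax`,
#'   `ymin`, `ymax`.
#' @seealso [zone_q()]
#' @export
bounding_box <- function(points) {
  p <- as_point_set(points)
  bb <- list(xmin = min(p$x), xmax = max(p$x),
             ymin = min(p$y), ymax = max(p$y))
  if (bb$xmin == bb$xmax || bb$ymin == bb$ymax)
    stop(errorCondition(
      "degenerate bounding box: data need at least two distinct x values and two distinct y values",
      class = c("zoneperm_degenerate_error", "error", "condition")))
  class(bb) <- "bounding_box"
  bb
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("bounding_box: x in [%g, %g], y in [%g, %g]\n",
              x$xmin, x$xmax, x$ymin, x$ymax))
  invisible(x)
}

.box_area <- function(bb) (bb$xmax - bb$xmin) * (bb$ymax - bb$ymin)

#' Reflect a point set into canonical (upper-left) orientation
#'
#' All four zones are handled by one algorithm written for the upper-left
#' corner; the other corners are mapped onto it by sign flips: A is the
#' identity, B negates x, C negates y, D negates both.  Applying the same
#' reflection twice is the identity, so results are mapped back with the
#' same call.
#'
#' @param points a [point_set()].
#' @param zone zone label `"A"`, `"B"`, `"C"` or `"D"`.
#' @return The reflected `point_set`.
#' @export
reflect_to_canonical <- function(points, zone) {
  p <- as_point_set(points)
  s <- .zone_signs(.match_zone(zone))
  if (s[1L] == 1 && s[2L] == 1) return(p)
  .ps(s[1L] * p$x, s[2L] * p$y)
}

#' Pareto staircase of a point set (canonical orientation)
#'
#' Constructs the ordered boundary vertices for the upper-left zone: start
#' at the minimum-x point; repeatedly move to the point with smallest x
#' among those with strictly greater x and strictly greater y; stop when no
#' such point remains.  The result is strictly increasing in both x and y
#' and is the Pareto front for (minimise x, maximise y): no input point lies
#' strictly above the polyline through the returned vertices.
#'
#' Ties are broken towards the zone: among points sharing the minimum x (or
#' tied at the smallest candidate x) the one with maximum y is taken, since
#' any lower choice would leave a data point inside the zone polygon.
#'
#' @param points a [point_set()] already in canonical orientation (see
#'   [reflect_to_canonical()]).
#' @return A numeric matrix with columns `x`, `y`, one row per boundary
#'   vertex in boundary order.  A single-row result is legal.
#' @export
pareto_sequence <- function(points) {
  p <- as_point_set(points)
  o <- order(p$x, -p$y)
  ys <- p$y[o]
  # after sorting by (x asc, y desc), the staircase is exactly the strict
  # running-maximum of y
  keep <- ys > c(-Inf, cummax(ys)[-length(ys)])
  cbind(x = p$x[o][keep], y = ys[keep])
}

#' Close a boundary polyline into the zone polygon
#'
#' Appends the canonical corner of the plot — the imaginary point at the
#' horizontal minimum and vertical maximum of the data — to the boundary
#' vertex sequence, forming the ring that encloses the upper-left no-data
#' zone.  Consecutive duplicate vertices (including across the ring closure)
#' are removed; a ring left with fewer than 3 distinct vertices is the
#' degenerate zero-area case (boundary starts at the corner itself).
#'
#' @param vertices two-column matrix of boundary vertices in order, as from
#'   [pareto_sequence()].
#' @param box a [bounding_box()].
#' @return A two-column matrix of ring vertices in order (the closing edge
#'   back to the first vertex is implicit).
#' @export
close_polygon <- function(vertices, box) {
  v <- rbind(as.matrix(vertices), c(box$xmin, box$ymax))
  if (nrow(v) > 1L) {
    same_prev <- c(FALSE, rowSums(abs(diff(v))) == 0)
    v <- v[!same_prev, , drop = FALSE]
    # ring wrap-around duplicate
    n <- nrow(v)
    if (n > 1L && all(v[n, ] == v[1L, ]))
      v <- v[-n, , drop = FALSE]
  }
  colnames(v) <- c("x", "y")
  v
}

#' Shoelace area of a simple polygon
#'
#' Absolute value of the signed shoelace sum, halved; independent of vertex
#' orientation.  Rings with fewer than 3 vertices have area 0.
#'
#' @param polygon two-column matrix of ring vertices in order (first vertex
#'   not repeated at the end).
#' @return Non-negative area in data units squared.
#' @export
shoelace_area <- function(polygon) {
  v <- as.matrix(polygon)
  if (nrow(v) < 3L) return(0)
  x <- v[, 1L]
  y <- v[, 2L]
  xn <- c(x[-1L], x[1L])
  yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

# ---- boundary providers ------------------------------------------------

.provider_registry <- new.env(parent = emptyenv())

#' Register or resolve a boundary-line provider
#'
#' The permutation test is agnostic to how the boundary line is defined: any
#' deterministic function mapping `(points, zone)` to a closed ring (a
#' two-column vertex matrix lying within the bounding box) can stand in for
#' the default Pareto staircase.  `register_boundary_provider()` installs a
#' named provider; `boundary_provider()` resolves a name (or passes a
#' function through).
#'
#' @param name provider name; `"staircase"` is built in.
#' @param fun `function(points, zone)` returning a ring matrix.
#' @return `boundary_provider()` returns the provider function.
#' @export
register_boundary_provider <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .provider_registry)
  invisible(name)
}

#' @rdname register_boundary_provider
#' @param provider provider name or `function(points, zone)`.
#' @export
boundary_provider <- function(provider = "staircase") {
  if (is.function(provider)) return(provider)
  if (is.character(provider) && length(provider) == 1L &&
      exists(provider, envir = .provider_registry))
    return(get(provider, envir = .provider_registry))
  stop("unknown boundary provider: ", provider)
}

# default provider: reflect -> Pareto staircase -> close -> reflect back
.staircase_ring <- function(points, zone) {
  zone <- .match_zone(zone)
  s <- .zone_signs(zone)
  cp <- reflect_to_canonical(points, zone)
  ring <- close_polygon(pareto_sequence(cp), bounding_box(cp))
  if (s[1L] == 1 && s[2L] == 1) return(ring)
  ring[, 1L] <- s[1L] * ring[, 1L]
  ring[, 2L] <- s[2L] * ring[, 2L]
  ring
}

#' Relative area Q of a no-data zone
#'
#' Builds the zone's boundary polygon and returns its absolute area together
#' with the test statistic Q, the zone area expressed relative to the area
#' of the data bounding box.  Q is invariant under translation and positive
#' rescaling of either axis and satisfies 0 <= Q < 1.
#'
#' @param points a [point_set()] (or coercible).
#' @param zone zone label: `"A"` upper-left, `"B"` upper-right, `"C"`
#'   lower-left, `"D"` lower-right.
#' @param provider boundary provider name or function; default the Pareto
#'   staircase (see [boundary_provider()]).
#' @return A list of class `zone_area` with elements `zone`, `absolute`
#'   (data units squared) and `Q` (dimensionless).
#' @examples
#' zone_q(point_set(c(0, 1), c(0, 1)), "A")$Q  # 0.5
#' @export
zone_q <- function(points, zone = "A", provider = "staircase") {
  p <- as_point_set(points)
  zone <- .match_zone(zone)
  pfun <- boundary_provider(provider)
  absolute <- shoelace_area(pfun(p, zone))
  structure(list(zone = zone, absolute = absolute,
                 Q = absolute / .box_area(bounding_box(p))),
            class = "zone_area")
}

#' @export
print.zone_area <- function(x, ...) {
  cat(sprintf("zone %s: absolute area = %g, Q = %g\n",
              x$zone, x$absolute, x$Q))
  invisible(x)
}

#' Boundary line and zone polygon for one corner
#'
#' Convenience wrapper bundling everything about one zone's observed
#' boundary: the boundary vertices (actual data points) in data space, the
#' zone's corner point, the closed ring, and the absolute and relative areas.
#'
#' @inheritParams zone_q
#' @return A list of class `zone_boundary` with elements `points`, `zone`,
#'   `vertices`, `corner`, `ring`, `absolute`, `Q`, `bbox`.
#' @export
zone_boundary <- function(points, zone = "A", provider = "staircase") {
  p <- as_point_set(points)
  zone <- .match_zone(zone)
  bb <- bounding_box(p)
  pfun <- boundary_provider(provider)
  ring <- pfun(p, zone)
  s <- .zone_signs(zone)
  cp <- reflect_to_canonical(p, zone)
  vx <- pareto_sequence(cp)
  vertices <- cbind(x = s[1L] * vx[, 1L], y = s[2L] * vx[, 2L])
  corner <- c(x = if (s[1L] == 1) bb$xmin else bb$xmax,
              y = if (s[2L] == 1) bb$ymax else bb$ymin)
  absolute <- shoelace_area(ring)
  structure(list(points = p, zone = zone, vertices = vertices,
                 corner = corner, ring = ring, absolute = absolute,
                 Q = absolute / .box_area(bb), bbox = bb),
            class = "zone_boundary")
}

#' @export
print.zone_boundary <- function(x, ...) {
  cat(sprintf("zone %s boundary: %d vertices, corner (%g, %g)\n",
              x$zone, nrow(x$vertices), x$corner[["x"]], x$corner[["y"]]))
  cat(sprintf("  absolute area = %g, Q = %g (n = %d points)\n",
              x$absolute, x$Q, nrow(x$points)))
  invisible(x)
}
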