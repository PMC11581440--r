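#' Construct a bivariate point set
#'
#' A `point_set` is the basic data container: paired observations of an
#' independent variable `x` and a dependent variable `y`, stored as a
#' two-column data frame.  Coordinates must be finite; incomplete rows are
#' expected to have been dropped at ingestion (see [read_xy()]).
#'
#' Zone tests additionally require at least 3 points and a non-degenerate
#' bounding box (at least two distinct x values and two distinct y values);
#' those preconditions are checked where the statistic is computed, not here,
#' so that small geometric building blocks can be exercised directly.
#'
#' @param x numeric vector, or a two-column object (matrix, data frame) when
#'   `y` is missing.
#' @param y numeric vector of the same length as `x`.
#' @return A data frame of class `point_set` with columns `x` and `y`.
#' @examples
#' point_set(c(0, 0.5, 1), c(0, 0.2, 1))
#' @export
point_set <- function(x, y = NULL) {
  if (is.null(y)) {
    x <- as.data.frame(x)
    if (ncol(x) < 2L)
      stop("need two columns (x, y) when `y` is not given")
    y <- x[[2L]]
    x <- x[[1L]]
  }
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must have equal length")
  if (length(x) < 1L)
    stop("empty point set")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("all coordinates must be finite; drop incomplete rows first (see read_xy)")
  .ps(x, y)
}

# fast internal constructor: no validation, no data.frame() overhead
.ps <- function(x, y) {
  structure(list(x = x, y = y),
            class = c("point_set", "data.frame"),
            row.names = .set_row_names(length(x)))
}

#' Coerce to a point set
#'
#' @param x an object with x/y coordinates: a `point_set`, a two-column
#'   matrix or data frame, or a list with components `x` and `y`.
#' @return A `point_set`.
#' @export
as_point_set <- function(x) {
  if (inherits(x, "point_set")) return(x)
  if (is.list(x) && !is.data.frame(x) && all(c("x", "y") %in% names(x)))
    return(point_set(x$x, x$y))
  point_set(x)
}

#' @export
print.point_set <- function(x, ...) {
  cat("point_set:", nrow(x), "observations\n")
  NextMethod()
}

.zone_labels <- c("A", "B", "C", "D")

.match_zone <- function(zone) {
  z <- toupper(as.character(zone))
  if (length(z) != 1L || !z %in% .zone_labels)
    stop("zone must be one of \"A\" (upper-left), \"B\" (upper-right), ",
         "\"C\" (lower-left), \"D\" (lower-right)")
  z
}

# sign flips taking a zone's corner onto the canonical upper-left corner
.zone_signs <- function(zone) {
  switch(zone,
         A = c(1, 1),
         B = c(-1, 1),
         C = c(1, -1),
         D = c(-1, -1))
}
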