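#' Read paired x-y data from a delimited text file
#'
#' Ingests CSV/TSV data with a header row, selects the x and y columns by
#' name or by position, coerces them to numeric and drops incomplete rows
#' (anything that does not parse to a finite number), reporting the number
#' dropped.  Fewer than 3 complete rows, or a degenerate bounding box (all
#' x equal or all y equal), is an error: the zone test is undefined there.
#'
#' @param path path to a delimited text file with a header row.
#' @param x_col,y_col column name (character) or 1-based position (numeric)
#'   of the independent and dependent variables; default the first two
#'   columns.
#' @param delimiter field delimiter, default comma.
#' @return A [point_set()] of the complete rows.
#' @export
read_xy <- function(path, x_col = 1L, y_col = 2L, delimiter = ",") {
  if (!file.exists(path))
    stop(errorCondition(paste0("input file not found: ", path),
                        class = c("zoneperm_io_error", "error", "condition")))
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  pick <- function(col, what) {
    if (is.character(col)) {
      if (!col %in% names(df))
        stop(errorCondition(
          sprintf("%s column \"%s\" not found (columns: %s)",
                  what, col, paste(names(df), collapse = ", ")),
          class = c("zoneperm_io_error", "error", "condition")))
      df[[col]]
    } else {
      col <- as.integer(col)
      if (is.na(col) || col < 1L || col > ncol(df))
        stop(errorCondition(
          sprintf("%s column index %s out of range (file has %d columns)",
                  what, col, ncol(df)),
          class = c("zoneperm_io_error", "error", "condition")))
      df[[col]]
    }
  }
  x <- suppressWarnings(as.numeric(pick(x_col, "x")))
  y <- suppressWarnings(as.numeric(pick(y_col, "y")))
  ok <- is.finite(x) & is.finite(y)
  if (any(!ok))
    message(sum(!ok), " incomplete row(s) dropped")
  if (sum(ok) < 3L)
    stop(errorCondition("insufficient data: fewer than 3 complete rows",
                        class = c("zoneperm_insufficient_error",
                                  "error", "condition")))
  p <- point_set(x[ok], y[ok])
  bounding_box(p)  # fail fast on a degenerate scatter
  p
}

.fmt_num <- function(x) {
  # full double precision; presentation rounding is the caller's concern
  ifelse(is.finite(x), sprintf("%.17g", x), as.character(x))
}

#' Write zone test results to TSV or JSON
#'
#' TSV output is the flat column schema of [run_zone_tests()]; JSON output
#' wraps the same rows in an object with a `metadata` block (package
#' version, optional run configuration echo, optional timestamp) so that a
#' result file plus the input data suffices to reproduce the run.  Numbers
#' are serialised in full double precision and the files are byte-stable
#' across identical runs (the timestamp is opt-in for that reason).
#'
#' @param results a non-empty `zone_test_result` data frame.
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @param config optional named list echoed verbatim into the JSON metadata
#'   (ignored for TSV).
#' @param timestamp logical; include a wall-clock timestamp in the JSON
#'   metadata.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("tsv", "json"),
                          config = NULL, timestamp = FALSE) {
  format <- match.arg(format)
  if (is.null(results) || nrow(results) == 0L)
    stop("empty results: nothing to write")
  df <- as.data.frame(results)
  if (format == "tsv") {
    out <- df
    num <- vapply(out, is.numeric, logical(1)) &
      !vapply(out, is.integer, logical(1))
    out[num] <- lapply(out[num], .fmt_num)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    meta <- list(package = "zoneperm",
                 version = as.character(utils::packageVersion("zoneperm")))
    if (timestamp)
      meta$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    if (!is.null(config))
      meta$config <- config
    jsonlite::write_json(list(metadata = meta, results = df), path,
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}
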