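#' ROI time-series container
#'
#' A thin container for a T x k matrix of region-of-interest (ROI) signals
#' sampled at a fixed repetition time (TR). Every stage of the pipeline
#' consumes and produces this shape: rows are timepoints, columns are
#' regions.
#'
#' @param x numeric matrix, T timepoints x k regions.
#' @param tr sampling interval in seconds (repetition time).
#' @param labels optional character vector of region labels (defaults to
#'   existing column names or `R1..Rk`).
#' @return An object of class `roi_ts`: the matrix with attributes `tr`
#'   and column names set to the region labels.
#' @examples
#' ts <- roi_ts(matrix(rnorm(200), 100, 2), tr = 2)
#' dim(ts); roi_tr(ts)
#' @export
roi_ts <- function(x, tr, labels = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  stopifnot(is.numeric(tr), length(tr) == 1L, tr > 0)
  if (is.null(labels)) {
    labels <- colnames(x)
    if (is.null(labels)) labels <- paste0("R", seq_len(ncol(x)))
  }
  stopifnot(length(labels) == ncol(x))
  colnames(x) <- labels
  attr(x, "tr") <- tr
  class(x) <- c("roi_ts", "matrix", "array")
  x
}

#' @rdname roi_ts
#' @export
roi_tr <- function(x) {
  tr <- attr(x, "tr")
  if (is.null(tr)) stop("object carries no TR; construct it with roi_ts()")
  tr
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("ROI time series: %d timepoints x %d regions, TR = %g s\n",
              nrow(x), ncol(x), roi_tr(x)))
  invisible(x)
}

# keep class + tr through single-bracket extraction of full columns
#' @export
`[.roi_ts` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "tr") <- attr(x, "tr")
    class(out) <- class(x)
  }
  out
}

#' Read and write ROI time-series matrices as delimited text
#'
#' One file per subject: tab-separated values, a header row of region
#' labels, T data rows of k columns.
#'
#' @param x an [roi_ts()] object.
#' @param path file path.
#' @param tr repetition time in seconds (required on read; the text format
#'   does not embed it).
#' @return `write_roi_ts` returns `path` invisibly; `read_roi_ts` returns
#'   an [roi_ts()].
#' @export
write_roi_ts <- function(x, path) {
  write.table(unclass(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_roi_ts
#' @export
read_roi_ts <- function(path, tr) {
  m <- as.matrix(read.delim(path, check.names = FALSE))
  roi_ts(m, tr = tr, labels = colnames(m))
}

# column-standardize (zero mean, unit sd); errors on zero-variance columns
standardize_ts <- function(x, what = "time series") {
  s <- apply(x, 2L, sd)
  if (any(!is.finite(s)) || any(s == 0)) {
    bad <- which(!is.finite(s) | s == 0)
    stop(sprintf("%s has zero-variance or non-finite column(s): %s",
                 what, paste(colnames(x)[bad], collapse = ", ")))
  }
  scale(x, center = TRUE, scale = s)
}
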