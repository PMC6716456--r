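#' Strength and variability network features for one subject
#'
#' Runs the connectivity stage on one subject's (latent or BOLD) time
#' series and flattens the results into a named feature vector following
#' the `{measure}.{flavor}.{scope}` schema, e.g. `cc.static.node:PFC`,
#' `spl.var.edge:PFC>INS`. Measures: `transitivity`, `effglob` (global),
#' `cc`, `effloc` (nodal), `spl`, `eb` (edge-level), each in `static`
#' (from the SEC graph) and `var` (temporal variance over DEC snapshots)
#' flavors; plus the raw connectivity features `sec.static.edge:*`
#' (signed GC) and `vdec.var.edge:*` (DGC variance) needed for
#' connectivity gating.
#'
#' @param ts [roi_ts()] for one subject.
#' @param p MVAR order.
#' @param forgetting Kalman forgetting factor for the dynamic stage.
#' @param burn_in,stride snapshot selection for the variability flavor.
#' @param deconvolve_first run blind deconvolution before connectivity.
#' @param band passband for deconvolution (when enabled).
#' @return named numeric vector.
#' @export
subject_features <- function(ts, p = 1L, forgetting = 0.99, burn_in = NULL,
                             stride = 1L, deconvolve_first = FALSE,
                             band = NULL) {
  if (deconvolve_first) ts <- deconvolve(ts, band = band)$latent
  conn <- connectivity(ts, p = p, forgetting = forgetting, burn_in = burn_in)
  ms <- static_metrics(to_graph(conn$sec))
  mv <- dynamic_metric_variance(conn$dec, burn_in = burn_in, stride = stride)
  labels <- colnames(ts)
  c(flatten_metrics(ms, "static", labels),
    flatten_metrics(mv, "var", labels),
    flatten_edges(unclass(conn$sec), "sec.static.edge", labels),
    flatten_edges(unclass(conn$vdec), "vdec.var.edge", labels))
}

flatten_edges <- function(m, prefix, labels) {
  k <- length(labels)
  idx <- which(row(m) != col(m))
  v <- m[idx]
  names(v) <- paste0(prefix, ":", labels[row(m)[idx]], ">",
                     labels[col(m)[idx]])
  v
}

flatten_metrics <- function(ms, flavor, labels) {
  out <- c(stats::setNames(ms$transitivity,
                           paste0("transitivity.", flavor, ".global")),
           stats::setNames(ms$global_efficiency,
                           paste0("effglob.", flavor, ".global")),
           stats::setNames(as.numeric(ms$cc),
                           paste0("cc.", flavor, ".node:", labels)),
           stats::setNames(as.numeric(ms$eff_loc),
                           paste0("effloc.", flavor, ".node:", labels)))
  c(out, flatten_edges(ms$spl, paste0("spl.", flavor, ".edge"), labels),
    flatten_edges(ms$eb, paste0("eb.", flavor, ".edge"), labels))
}

#' Feature table for a whole cohort
#'
#' Applies [subject_features()] to every subject and binds the rows; the
#' result (subjects x features) together with the manifest is the input
#' to the group-statistics and prediction stages.
#'
#' @param cohort a [simulate_cohort()] result, or a named list of
#'   [roi_ts()].
#' @param use for a simulated cohort: `"bold"` (observed series) or
#'   `"latent"` (the simulated neural series; requires
#'   `keep_latent = TRUE` at simulation time).
#' @param ... passed to [subject_features()].
#' @return data.frame of features, rownames = subject ids.
#' @export
cohort_features <- function(cohort, use = c("bold", "latent"), ...) {
  use <- match.arg(use)
  series <- if (inherits(cohort, "cohort")) {
    if (use == "latent") {
      if (is.null(cohort$latent))
        stop("cohort was simulated without keep_latent = TRUE")
      stats::setNames(cohort$latent, names(cohort$bold))
    } else cohort$bold
  } else cohort
  rows <- lapply(series, subject_features, ...)
  out <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  rownames(out) <- names(series)
  out
}

# split "{measure}.{flavor}.{scope}" names into their parts
parse_feature_names <- function(nm) {
  parts <- strsplit(nm, ".", fixed = TRUE)
  data.frame(feature = nm,
             measure = vapply(parts, `[[`, "", 1L),
             flavor = vapply(parts, `[[`, "", 2L),
             scope = vapply(parts, function(p)
               paste(p[-(1:2)], collapse = "."), ""),
             stringsAsFactors = FALSE)
}
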