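#' Multiple-comparison accounting for a k-region network
#'
#' The correction budget of the selection framework: k segregation
#' comparisons (one per region), `k^2 - k` integration comparisons (one
#' per ordered region pair), each tested on both the static (strength)
#' and dynamic-variance (variability) networks.
#'
#' @param k number of regions.
#' @return named integer vector `(n_segregation, n_integration, n_total)`
#'   with `n_total = 2 * (n_segregation + n_integration)`.
#' @examples
#' count_comparisons(125)  # 125, 15500, 31250
#' @export
count_comparisons <- function(k) {
  stopifnot(k >= 2)
  n_seg <- as.integer(k)
  n_int <- as.integer(k^2 - k)
  c(n_segregation = n_seg, n_integration = n_int,
    n_total = 2L * (n_seg + n_int))
}

# merge race categories with < 2 subjects (in the analyzed subset) into
# "other", then dummy-code with the largest category as reference
race_dummies <- function(race) {
  race <- as.character(race)
  tab <- table(race)
  race[race %in% names(tab)[tab < 2]] <- "other"
  tab <- sort(table(race), decreasing = TRUE)
  if (length(tab) < 2) return(NULL)
  f <- factor(race, levels = names(tab))
  stats::model.matrix(~f)[, -1, drop = FALSE]
}

# numeric covariate matrix (age, education, race dummies, motion) for the
# given manifest rows
covariate_matrix <- function(manifest,
                             covariates = c("age", "education", "race",
                                            "motion")) {
  cols <- list()
  for (cv in covariates) {
    if (cv == "race") {
      rd <- race_dummies(manifest$race)
      if (!is.null(rd)) cols[[cv]] <- rd
    } else cols[[cv]] <- matrix(manifest[[cv]], ncol = 1,
                                dimnames = list(NULL, cv))
  }
  if (!length(cols)) return(NULL)
  do.call(cbind, cols)
}

# vectorized covariate-adjusted two-group comparison over a feature matrix:
# per feature, linear model feature ~ group + covariates; two-sided p for
# the group term; adjusted means at covariate grand means
pair_stats_matrix <- function(F, group01, covs) {
  X <- cbind(1, group01)
  if (!is.null(covs)) X <- cbind(X, covs)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stop(sprintf("collinear covariates in pairwise model: %s",
                 paste(bad, collapse = ", ")))
  }
  B <- qr.coef(q, F)                    # ncol(X) x m
  R <- F - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(R^2) / df
  XtXi <- chol2inv(qr.R(q)[, order(q$pivot), drop = FALSE])
  se <- sqrt(sigma2 * XtXi[2, 2])
  tstat <- B[2, ] / se
  p <- 2 * stats::pt(-abs(tstat), df)
  cm <- if (is.null(covs)) NULL else colMeans(covs)
  base <- B[1, ] + if (is.null(cm)) 0 else as.numeric(cm %*%
    B[-(1:2), , drop = FALSE])
  data.frame(p = p, direction = sign(B[2, ]),
             adj_mean_1 = base, adj_mean_2 = base + B[2, ],
             row.names = colnames(F))
}

#' Covariate-adjusted pairwise group comparison for one feature
#'
#' Linear model `feature ~ group + age + education + race + motion` on the
#' two groups; two-sided p-value for the group term; adjusted group means
#' evaluated at the covariate grand means. Race categories with fewer
#' than 2 subjects in the pair are merged into "other".
#'
#' @param feature numeric vector over the subjects of the two groups.
#' @param group two-level factor (same length).
#' @param covariates data.frame with columns `age`, `education`, `race`,
#'   `motion` (any subset usable via `use`).
#' @param use which covariates to adjust for.
#' @return list `p`, `adjusted_means` (named, in level order),
#'   `direction` (sign of the level-2 minus level-1 adjusted difference).
#' @export
ancova_pair <- function(feature, group, covariates = NULL,
                        use = c("age", "education", "race", "motion")) {
  group <- droplevels(factor(group))
  stopifnot(nlevels(group) == 2L)
  if (min(table(group)) < 3L) stop("each group needs at least 3 subjects")
  covs <- if (is.null(covariates)) NULL else
    covariate_matrix(covariates, covariates = use)
  res <- pair_stats_matrix(matrix(feature, ncol = 1,
                                  dimnames = list(NULL, "f")),
                           as.numeric(group) - 1, covs)
  list(p = res$p,
       adjusted_means = stats::setNames(c(res$adj_mean_1, res$adj_mean_2),
                                        levels(group)),
       direction = res$direction)
}

#' Benjamini-Hochberg FDR correction with an explicit comparison budget
#'
#' Step-up BH over the full comparison budget `m`, which may exceed the
#' number of p-values actually supplied (the remaining budget is treated
#' as untested comparisons, making the correction conservative — this is
#' how a k-region analysis accounts for all `k^2` potential tests).
#'
#' @param p_values numeric vector of p-values.
#' @param q FDR level.
#' @param m correction budget (default: number of p-values).
#' @return list `q_values`, `significant` (logical mask).
#' @export
fdr_bh <- function(p_values, q = 0.05, m = length(p_values)) {
  m <- max(m, length(p_values))
  qv <- p.adjust(p_values, method = "BH", n = m)
  list(q_values = qv, significant = qv <= q)
}

#' Trend conformance of adjusted group means
#'
#' Strength (static) features conform when the adjusted means are
#' strictly monotone across control -> PTSD -> PCS+PTSD in one direction:
#' increasing is labeled `inflation`, decreasing `deflation`. Variability
#' features conform only when strictly decreasing (`rigidity`). Ties break
#' conformance. The relaxed rule (for features expected to differ from
#' control but not between the clinical groups) only requires both
#' clinical groups on the same side of control (and below control for
#' variability).
#'
#' @param means length-3 numeric, adjusted means in group order (control,
#'   ptsd, pcs_ptsd).
#' @param flavor `"static"` (strength) or `"var"` (variability).
#' @param relaxed use the relaxed rule.
#' @return list `conforming` (logical), `label` (`"inflation"`,
#'   `"deflation"`, `"rigidity"`, or `NA`).
#' @export
trend_filter <- function(means, flavor = c("static", "var"),
                         relaxed = FALSE) {
  flavor <- match.arg(flavor)
  stopifnot(length(means) == 3L)
  d <- diff(means)
  if (flavor == "var") {
    ok <- if (relaxed) means[2] < means[1] && means[3] < means[1]
          else all(d < 0)
    return(list(conforming = ok, label = if (ok) "rigidity" else NA_character_))
  }
  if (relaxed) {
    up <- means[2] > means[1] && means[3] > means[1]
    dn <- means[2] < means[1] && means[3] < means[1]
  } else {
    up <- all(d > 0)
    dn <- all(d < 0)
  }
  list(conforming = up || dn,
       label = if (up) "inflation" else if (dn) "deflation" else NA_character_)
}

#' Intersection of local-measure hit sets
#'
#' Both local measures of a domain must flag a node (clustering
#' coefficient and local efficiency) or an edge (shortest path length and
#' edge betweenness) for it to be retained — the conservative overlap
#' rule.
#'
#' @param a,b character vectors of selected scopes.
#' @return their intersection.
#' @export
intersect_local <- function(a, b) intersect(a, b)

pair_names <- c(cp = "control_vs_ptsd", ccp = "control_vs_pcs_ptsd",
                pcp = "ptsd_vs_pcs_ptsd")

# three-group adjusted means at covariate grand means, vectorized
adjusted_means_3g <- function(F, group, covs) {
  g <- factor(group, levels = group_levels)
  X <- cbind(1, as.numeric(g == "ptsd"), as.numeric(g == "pcs_ptsd"))
  if (!is.null(covs)) X <- cbind(X, covs)
  q <- qr(X)
  if (q$rank < ncol(X)) stop("collinear covariates in three-group model")
  B <- qr.coef(q, F)
  cm <- if (is.null(covs)) NULL else colMeans(covs)
  base <- B[1, ] + if (is.null(cm)) 0 else
    as.numeric(cm %*% B[-(1:3), , drop = FALSE])
  out <- cbind(control = base, ptsd = base + B[2, ],
               pcs_ptsd = base + B[3, ])
  rownames(out) <- colnames(F)
  out
}

#' Hypothesis-driven feature selection across three groups
#'
#' The full selection framework. For every feature: covariate-adjusted
#' pairwise comparisons (control vs PTSD, control vs PCS+PTSD, PTSD vs
#' PCS+PTSD) on both flavors — six cells per network measure — with BH
#' FDR correction applied per comparison family at the full comparison
#' budget of [count_comparisons()] (k for nodal measures, k^2 - k for
#' edge measures). A measure-scope unit is *hypothesis-2* when all six
#' cells are significant and its adjusted means are strictly
#' trend-conforming (monotone strength, strictly decreasing variability);
#' it is *hypothesis-1* when the four control-vs-clinical cells are
#' significant, neither PTSD-vs-PCS+PTSD cell is, and the relaxed trend
#' holds (both clinical groups shifted the same way from control). Nodes
#' must be selected by both clustering coefficient and local efficiency;
#' edges by both shortest path length and edge betweenness. Finally,
#' selected edges are gated on the raw connectivity: an edge is retained
#' only when its signed static connectivity and its dynamic-connectivity
#' variance independently show the same hypothesis pattern.
#'
#' @param features data.frame from [cohort_features()] (rows = subjects).
#' @param manifest cohort manifest with `group` and covariate columns.
#' @param q FDR level.
#' @param covariates covariates to adjust for (subset of age, education,
#'   race, motion).
#' @return `hypothesis_result` list: `cells` (per feature x pair p/q/
#'   significance/direction), `adjusted_means`, `units` (per
#'   measure-scope flags), `h1_nodes`, `h2_nodes`, `h1_edges`,
#'   `h2_edges`, `gated_edges`, `trend_labels`, `q`, `budget`.
#' @export
apply_hypotheses <- function(features, manifest, q = 0.05,
                             covariates = c("age", "education", "race",
                                            "motion")) {
  F <- as.matrix(features)
  stopifnot(nrow(F) == nrow(manifest))
  meta <- parse_feature_names(colnames(F))
  group <- factor(manifest$group, levels = group_levels)
  k <- length(unique(meta$scope[meta$measure == "cc"]))
  budget <- count_comparisons(k)
  scope_budget <- function(measure) {
    ifelse(measure %in% c("transitivity", "effglob"), 1L,
           ifelse(measure %in% c("cc", "effloc"), budget["n_segregation"],
                  budget["n_integration"]))
  }

  # pairwise cells
  cells <- NULL
  for (pr in names(pair_names)) {
    gl <- switch(pr, cp = c("control", "ptsd"),
                 ccp = c("control", "pcs_ptsd"),
                 pcp = c("ptsd", "pcs_ptsd"))
    idx <- group %in% gl
    mf <- manifest[idx, , drop = FALSE]
    covs <- covariate_matrix(mf, covariates = covariates)
    st <- pair_stats_matrix(F[idx, , drop = FALSE],
                            as.numeric(group[idx] == gl[2]), covs)
    st$feature <- rownames(st)
    st$pair <- pr
    cells <- rbind(cells, st)
  }
  cells <- merge(cells, meta, by = "feature", sort = FALSE)

  # BH per (pair, measure, flavor) family at the family's scope budget
  cells$q_value <- NA_real_
  fam <- interaction(cells$pair, cells$measure, cells$flavor, drop = TRUE)
  for (f in levels(fam)) {
    i <- which(fam == f)
    m <- scope_budget(cells$measure[i[1]])
    cells$q_value[i] <- fdr_bh(cells$p[i], q = q, m = m)$q_values
  }
  cells$significant <- cells$q_value <= q

  covs_all <- covariate_matrix(manifest, covariates = covariates)
  am <- adjusted_means_3g(F, group, covs_all)

  # measure-scope units: pair static/var flavors of the six measures and
  # the raw sec/vdec connectivity features
  units <- unit_table(cells, am, q)
  sel <- function(measure, col) units$scope[units$measure == measure &
                                              units[[col]]]
  h1_nodes <- intersect_local(sel("cc", "h1"), sel("effloc", "h1"))
  h2_nodes <- intersect_local(sel("cc", "h2"), sel("effloc", "h2"))
  h1_edges <- intersect_local(sel("spl", "h1"), sel("eb", "h1"))
  h2_edges <- intersect_local(sel("spl", "h2"), sel("eb", "h2"))
  gated <- connectivity_gate(
    list(h1 = h1_edges, h2 = h2_edges),
    units[units$measure == "conn", , drop = FALSE])
  labels <- units$label_static
  names(labels) <- paste0(units$measure, ":", units$scope)
  structure(list(cells = cells, adjusted_means = am, units = units,
                 h1_nodes = h1_nodes, h2_nodes = h2_nodes,
                 h1_edges = h1_edges, h2_edges = h2_edges,
                 gated_edges = gated, trend_labels = labels,
                 q = q, budget = budget, k = k),
            class = "hypothesis_result")
}

# build the per-unit table: for each measure-scope, 6 cells (3 pairs x
# static/var flavor), significance pattern, trend conformance, h1/h2 flags.
# The raw connectivity unit ("conn") pairs sec.static with vdec.var.
unit_table <- function(cells, am, q) {
  cells$umeasure <- ifelse(cells$measure %in% c("sec", "vdec"), "conn",
                           cells$measure)
  key <- paste(cells$umeasure, cells$scope)
  out <- NULL
  for (kk in unique(key)) {
    cc <- cells[key == kk, , drop = FALSE]
    um <- cc$umeasure[1]
    sig <- function(pr, fl) {
      i <- cc$pair == pr & cc$flavor == fl
      any(i) && all(cc$significant[i])
    }
    sv <- vapply(names(pair_names), sig, TRUE, fl = "static")
    vv <- vapply(names(pair_names), sig, TRUE, fl = "var")
    fs <- cc$feature[cc$flavor == "static"][1]
    fv <- cc$feature[cc$flavor == "var"][1]
    ms <- if (!is.na(fs)) am[fs, ] else rep(NA_real_, 3)
    mv <- if (!is.na(fv)) am[fv, ] else rep(NA_real_, 3)
    t2s <- trend_filter(ms, "static"); t2v <- trend_filter(mv, "var")
    t1s <- trend_filter(ms, "static", relaxed = TRUE)
    t1v <- trend_filter(mv, "var", relaxed = TRUE)
    h2 <- all(sv) && all(vv) && t2s$conforming && t2v$conforming
    h1 <- !h2 && sv["cp"] && sv["ccp"] && vv["cp"] && vv["ccp"] &&
      !sv["pcp"] && !vv["pcp"] && t1s$conforming && t1v$conforming
    out <- rbind(out, data.frame(
      measure = um, scope = cc$scope[1],
      sig_static_cp = sv["cp"], sig_static_ccp = sv["ccp"],
      sig_static_pcp = sv["pcp"], sig_var_cp = vv["cp"],
      sig_var_ccp = vv["ccp"], sig_var_pcp = vv["pcp"],
      h1 = h1, h2 = h2,
      label_static = if (h2) t2s$label else if (h1) t1s$label
                     else NA_character_,
      stringsAsFactors = FALSE, row.names = NULL))
  }
  out
}

#' Gate selected edges on raw connectivity significance
#'
#' Retains only those selected edges whose raw static connectivity (SEC)
#' and dynamic-connectivity variance (vDEC) independently pass the same
#' hypothesis pattern under the identical pairwise FDR + trend scheme —
#' selected paths must also be disturbed in plain effective connectivity,
#' not only in network terms.
#'
#' @param edge_sets list with character vectors `h1` and `h2` of edge
#'   scopes (e.g. `"edge:PFC>INS"`).
#' @param conn_units the `units` rows for the raw-connectivity unit (from
#'   [apply_hypotheses()]'s unit table, measure `"conn"`).
#' @return character vector of gated edges.
#' @export
connectivity_gate <- function(edge_sets, conn_units) {
  ok1 <- conn_units$scope[conn_units$h1]
  ok2 <- conn_units$scope[conn_units$h2]
  c(intersect(edge_sets$h1, ok1), intersect(edge_sets$h2, ok2))
}
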