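#' Build a weighted directed graph from a connectivity matrix
#'
#' Takes absolute values of the (signed) connectivity and rescales so the
#' maximum weight is 1; an all-zero matrix stays zero. Node labels come
#' from the matrix dimnames. All six network measures operate on this
#' normalized |connectivity| graph, making them invariant to the overall
#' connectivity scale.
#'
#' @param conn_matrix square numeric matrix (zero diagonal).
#' @param labels optional node labels.
#' @return `weighted_digraph`: list(`W` nonnegative k x k, `labels`).
#' @export
to_graph <- function(conn_matrix, labels = NULL) {
  W <- abs(as.matrix(conn_matrix))
  stopifnot(nrow(W) == ncol(W))
  diag(W) <- 0
  mx <- max(W)
  if (mx > 0) W <- W / mx
  if (is.null(labels)) {
    labels <- rownames(conn_matrix)
    if (is.null(labels)) labels <- paste0("R", seq_len(nrow(W)))
  }
  dimnames(W) <- list(labels, labels)
  structure(list(W = W, labels = labels), class = "weighted_digraph")
}

as_digraph <- function(g) {
  if (inherits(g, "weighted_digraph")) g else to_graph(g)
}

#' Weighted-directed segregation measures
#'
#' Fagiolo-style formulations on cube-root weights: `transitivity` is the
#' whole-network ratio of directed triangle intensity to possible
#' triangles; `clustering_coefficient` is the per-node version;
#' `local_efficiency` is the global efficiency of each node's
#' neighborhood subgraph. Transitivity is undefined (`NA`) for fewer than
#' 3 nodes.
#'
#' @param g a [to_graph()] object (or a connectivity matrix, converted).
#' @return `transitivity`: scalar; `clustering_coefficient`,
#'   `local_efficiency`: length-k named vectors.
#' @export
transitivity <- function(g) {
  g <- as_digraph(g)
  .clustering_cpp(g$W)$transitivity
}

#' @rdname transitivity
#' @export
clustering_coefficient <- function(g) {
  g <- as_digraph(g)
  cc <- .clustering_cpp(g$W)$cc
  names(cc) <- g$labels
  cc
}

#' @rdname transitivity
#' @export
local_efficiency <- function(g) {
  g <- as_digraph(g)
  eff <- .local_efficiency_cpp(g$W)
  names(eff) <- g$labels
  eff
}

#' Weighted-directed integration measures
#'
#' Edge length is the inverse weight (`1/w`; zero weight = absent edge).
#' `distance_matrix` gives shortest directed path lengths between all
#' ordered pairs (`+Inf` when unreachable, 0 on the diagonal).
#' `global_efficiency` is the mean inverse distance over ordered pairs
#' (unreachable pairs contribute 0). `edge_betweenness` counts, for every
#' edge, the number of shortest directed paths — over all ordered
#' source-target pairs, including all tied shortest paths — that traverse
#' it.
#'
#' @param g a [to_graph()] object (or connectivity matrix).
#' @return `distance_matrix`, `edge_betweenness`: k x k matrices;
#'   `global_efficiency`: scalar.
#' @export
distance_matrix <- function(g) {
  g <- as_digraph(g)
  D <- .dist_counts_cpp(g$W)$d
  dimnames(D) <- list(g$labels, g$labels)
  D
}

#' @rdname distance_matrix
#' @export
global_efficiency <- function(g) {
  g <- as_digraph(g)
  .global_efficiency_cpp(.dist_counts_cpp(g$W)$d)
}

#' @rdname distance_matrix
#' @export
edge_betweenness <- function(g) {
  g <- as_digraph(g)
  dc <- .dist_counts_cpp(g$W)
  EB <- .edge_betweenness_cpp(g$W, dc$d, dc$n_paths)
  dimnames(EB) <- list(g$labels, g$labels)
  EB
}

#' All six network measures of one graph
#'
#' @param g a [to_graph()] object or connectivity matrix (e.g. a SEC
#'   matrix).
#' @return `metric_set` list: `transitivity`, `global_efficiency`
#'   (scalars), `cc`, `eff_loc` (k-vectors), `spl`, `eb` (k x k
#'   matrices).
#' @export
static_metrics <- function(g) {
  g <- as_digraph(g)
  dc <- .dist_counts_cpp(g$W)
  cl <- .clustering_cpp(g$W)
  cc <- cl$cc; names(cc) <- g$labels
  el <- .local_efficiency_cpp(g$W); names(el) <- g$labels
  D <- dc$d; dimnames(D) <- list(g$labels, g$labels)
  EB <- .edge_betweenness_cpp(g$W, dc$d, dc$n_paths)
  dimnames(EB) <- list(g$labels, g$labels)
  structure(list(transitivity = cl$transitivity,
                 global_efficiency = .global_efficiency_cpp(dc$d),
                 cc = cc, eff_loc = el, spl = D, eb = EB),
            class = "metric_set")
}

# population variance of a trajectory that may contain Inf (unreachable
# snapshots): constant trajectories have variance 0, mixed finite/Inf give
# Inf
traj_var <- function(x) {
  if (all(x == x[1])) return(0)
  if (any(!is.finite(x))) return(Inf)
  pop_var(x)
}

#' Temporal variance of network measures over dynamic-connectivity snapshots
#'
#' Treats each retained timepoint of the DGC tensor as a network snapshot,
#' computes all six measures on each snapshot graph, and reduces every
#' measure's trajectory to its (population) variance over time — the
#' "flexibility" of that network property. All-zero snapshots are valid
#' (metrics are zero), not errors.
#'
#' @param dec a [dynamic_gc()] result or k x k x T array.
#' @param burn_in discarded prefix (default [default_burn_in()]).
#' @param stride keep every stride-th snapshot (runtime/fidelity
#'   trade-off).
#' @return `metric_variance_set` list with the same slots as
#'   [static_metrics()], each holding the variance over snapshots, plus
#'   `n_snapshots`.
#' @export
dynamic_metric_variance <- function(dec, burn_in = NULL, stride = 1L) {
  dgc <- if (inherits(dec, "dec_series")) dec$dgc else dec
  Tn <- dim(dgc)[3]; k <- dim(dgc)[1]
  if (is.null(burn_in)) burn_in <- default_burn_in(Tn)
  keep <- seq.int(burn_in + 1L, Tn, by = stride)
  if (length(keep) < 30L)
    stop("fewer than 30 snapshots after burn-in/stride")
  labels <- dimnames(dgc)[[1]]
  if (is.null(labels)) labels <- paste0("R", seq_len(k))
  n <- length(keep)
  tr_t <- numeric(n); ge_t <- numeric(n)
  cc_t <- matrix(0, n, k); el_t <- matrix(0, n, k)
  spl_t <- array(0, c(k, k, n)); eb_t <- array(0, c(k, k, n))
  for (s in seq_len(n)) {
    ms <- static_metrics(to_graph(dgc[, , keep[s]], labels = labels))
    tr_t[s] <- ms$transitivity; ge_t[s] <- ms$global_efficiency
    cc_t[s, ] <- ms$cc; el_t[s, ] <- ms$eff_loc
    spl_t[, , s] <- ms$spl; eb_t[, , s] <- ms$eb
  }
  tr_t[is.na(tr_t)] <- 0  # all-zero snapshots: no triangles
  spl_v <- apply(spl_t, c(1, 2), traj_var)
  eb_v <- apply(eb_t, c(1, 2), traj_var)
  dimnames(spl_v) <- dimnames(eb_v) <- list(labels, labels)
  cc_v <- apply(cc_t, 2L, traj_var); names(cc_v) <- labels
  el_v <- apply(el_t, 2L, traj_var); names(el_v) <- labels
  structure(list(transitivity = traj_var(tr_t),
                 global_efficiency = traj_var(ge_t),
                 cc = cc_v, eff_loc = el_v, spl = spl_v, eb = eb_v,
                 n_snapshots = n, burn_in = burn_in, stride = stride),
            class = "metric_variance_set")
}
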