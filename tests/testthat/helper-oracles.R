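# Brute-force reference implementations for the graph measures, used as
# independent oracles on small graphs (k <= 6). All are written from the
# definitions with explicit loops / exhaustive path enumeration, sharing no
# code with the package's compiled implementations.

random_digraph <- function(k, p_edge = 0.7, seed = 1) {
  set.seed(seed)
  W <- matrix(runif(k * k, 0.2, 1) * (runif(k * k) < p_edge), k, k)
  diag(W) <- 0
  W / max(W, 1e-12)
}

# all simple directed paths from s to t as lists of node sequences
all_simple_paths <- function(W, s, t) {
  k <- nrow(W)
  out <- list()
  walk <- function(path) {
    u <- path[length(path)]
    if (u == t && length(path) > 1) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    for (v in seq_len(k)) {
      if (W[u, v] > 0 && !(v %in% path)) walk(c(path, v))
    }
  }
  walk(s)
  out
}

path_length <- function(W, path) {
  sum(1 / W[cbind(path[-length(path)], path[-1])])
}

oracle_distances <- function(W) {
  k <- nrow(W)
  D <- matrix(Inf, k, k)
  diag(D) <- 0
  for (s in seq_len(k)) for (t in seq_len(k)) {
    if (s == t) next
    ps <- all_simple_paths(W, s, t)
    if (length(ps)) D[s, t] <- min(vapply(ps, path_length, 0, W = W))
  }
  D
}

oracle_global_efficiency <- function(W) {
  D <- oracle_distances(W)
  k <- nrow(W)
  if (k < 2) return(0)
  s <- 0
  for (i in seq_len(k)) for (j in seq_len(k))
    if (i != j && is.finite(D[i, j])) s <- s + 1 / D[i, j]
  s / (k * (k - 1))
}

# edge betweenness as raw counts of shortest paths (all ties) through each
# edge, by exhaustive enumeration
oracle_edge_betweenness <- function(W, tol = 1e-9) {
  k <- nrow(W)
  EB <- matrix(0, k, k)
  for (s in seq_len(k)) for (t in seq_len(k)) {
    if (s == t) next
    ps <- all_simple_paths(W, s, t)
    if (!length(ps)) next
    lens <- vapply(ps, path_length, 0, W = W)
    best <- min(lens)
    for (pi in which(lens <= best + tol * max(1, best))) {
      path <- ps[[pi]]
      for (e in seq_len(length(path) - 1))
        EB[path[e], path[e + 1]] <- EB[path[e], path[e + 1]] + 1
    }
  }
  EB
}

# Fagiolo-style directed weighted clustering by explicit triple loops
oracle_clustering <- function(W) {
  k <- nrow(W)
  Wc <- W^(1 / 3)
  cc <- numeric(k)
  ti <- numeric(k)
  denom <- numeric(k)
  for (i in seq_len(k)) {
    t <- 0
    for (j in seq_len(k)) for (h in seq_len(k)) {
      if (j == i || h == i || h == j) next
      t <- t + (Wc[i, j] + Wc[j, i]) * (Wc[i, h] + Wc[h, i]) *
        (Wc[j, h] + Wc[h, j])
    }
    ti[i] <- t / 2
    dtot <- sum((W[i, -i] > 0) + (W[-i, i] > 0))
    dbi <- sum(W[i, -i] > 0 & W[-i, i] > 0)
    denom[i] <- dtot * (dtot - 1) - 2 * dbi
    cc[i] <- if (denom[i] > 0) ti[i] / denom[i] else 0
  }
  list(cc = cc,
       transitivity = if (k < 3 || sum(denom) <= 0) NA_real_
                      else sum(ti) / sum(denom))
}

oracle_local_efficiency <- function(W) {
  k <- nrow(W)
  eff <- numeric(k)
  for (i in seq_len(k)) {
    nb <- which((W[i, ] > 0 | W[, i] > 0) & seq_len(k) != i)
    if (length(nb) < 2) next
    eff[i] <- oracle_global_efficiency(W[nb, nb, drop = FALSE])
  }
  eff
}
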