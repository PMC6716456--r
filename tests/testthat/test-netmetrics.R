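test_that("graph construction normalizes absolute weights and is scale invariant", {
  m <- matrix(c(0, 0.5, -0.5, 0), 2, 2, byrow = TRUE)
  g <- to_graph(m)
  expect_equal(unname(g$W), matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE))
  g7 <- to_graph(7 * m)
  expect_equal(g$W, g7$W)
  g0 <- to_graph(matrix(0, 3, 3))
  expect_equal(max(g0$W), 0)
})

test_that("closed-form graphs give known metric values", {
  # complete unit-weight digraph
  K <- matrix(1, 4, 4); diag(K) <- 0
  g <- to_graph(K)
  expect_equal(transitivity(g), 1)
  expect_equal(unname(clustering_coefficient(g)), rep(1, 4))
  expect_equal(global_efficiency(g), 1)
  D <- distance_matrix(g)
  expect_equal(unname(D[upper.tri(D) | lower.tri(D)]), rep(1, 12))
  # complete 3-node digraph: each edge carries only its own pair's path
  K3 <- matrix(1, 3, 3); diag(K3) <- 0
  expect_equal(unname(edge_betweenness(to_graph(K3))[K3 > 0]), rep(1, 6))
  # directed 4-cycle has no triangles
  C4 <- matrix(0, 4, 4); C4[cbind(1:4, c(2, 3, 4, 1))] <- 1
  expect_equal(transitivity(to_graph(C4)), 0)
  expect_equal(unname(clustering_coefficient(to_graph(C4))), rep(0, 4))
})

test_that("chain graph distances, reachability and edge betweenness", {
  ch <- matrix(0, 3, 3); ch[1, 2] <- ch[2, 3] <- 1
  g <- to_graph(ch)
  D <- distance_matrix(g)
  expect_equal(D[1, 3], 2)
  expect_equal(D[3, 1], Inf)
  EB <- edge_betweenness(g)
  expect_equal(EB[1, 2], 2)  # paths 1->2 and 1->3
  expect_equal(EB[2, 3], 2)  # paths 2->3 and 1->3
  expect_equal(global_efficiency(g), (1 + 1 + 1 / 2) / 6)
})

test_that("all six measures match brute-force oracles on random digraphs", {
  cases <- expand.grid(k = 4:6, rep = 1:10)
  for (i in seq_len(nrow(cases))) {
    W <- random_digraph(cases$k[i], p_edge = 0.6,
                        seed = 100 * cases$k[i] + cases$rep[i])
    g <- to_graph(W)
    ms <- static_metrics(g)
    or <- oracle_clustering(g$W)
    expect_equal(unname(ms$cc), or$cc, tolerance = 1e-10)
    expect_equal(ms$transitivity, or$transitivity, tolerance = 1e-10)
    expect_equal(unname(ms$spl), oracle_distances(g$W), tolerance = 1e-10)
    expect_equal(ms$global_efficiency, oracle_global_efficiency(g$W),
                 tolerance = 1e-10)
    expect_equal(unname(ms$eb), oracle_edge_betweenness(g$W),
                 tolerance = 1e-10)
    expect_equal(unname(ms$eff_loc), oracle_local_efficiency(g$W),
                 tolerance = 1e-10)
  }
})

test_that("node relabeling permutes nodal outputs and fixes global scalars", {
  for (r in 1:20) {
    W <- random_digraph(6, seed = 300 + r)
    g <- to_graph(W)
    ms <- static_metrics(g)
    set.seed(400 + r)
    pm <- sample(6)
    gp <- to_graph(W[pm, pm])
    msp <- static_metrics(gp)
    expect_equal(msp$transitivity, ms$transitivity, tolerance = 1e-12)
    expect_equal(msp$global_efficiency, ms$global_efficiency,
                 tolerance = 1e-12)
    expect_equal(unname(msp$cc), unname(ms$cc[pm]), tolerance = 1e-12)
    expect_equal(unname(msp$eff_loc), unname(ms$eff_loc[pm]),
                 tolerance = 1e-12)
    expect_equal(unname(msp$spl), unname(ms$spl[pm, pm]), tolerance = 1e-12)
    expect_equal(unname(msp$eb), unname(ms$eb[pm, pm]), tolerance = 1e-12)
  }
})

test_that("raising one edge weight never lengthens any shortest path", {
  for (r in 1:10) {
    W <- random_digraph(6, seed = 500 + r)
    D0 <- distance_matrix(to_graph(W))
    set.seed(600 + r)
    e <- which(W > 0 & W < 0.5)[1]
    if (is.na(e)) next
    W2 <- W
    W2[e] <- W2[e] + (1 - W2[e]) * 0.9
    # compare on identical normalization: scale both to the same max weight
    D1 <- distance_matrix(structure(list(W = W2 / max(W2),
                                         labels = paste0("R", 1:6)),
                                    class = "weighted_digraph"))
    D0s <- distance_matrix(structure(list(W = W / max(W2),
                                          labels = paste0("R", 1:6)),
                                     class = "weighted_digraph"))
    expect_true(all(D1 <= D0s + 1e-9))
  }
})

test_that("snapshot metric variance is exact for two-point alternation", {
  k <- 5
  A <- random_digraph(k, seed = 701)
  B <- random_digraph(k, seed = 702)
  dgc <- array(0, c(k, k, 60))
  for (t in 1:60) dgc[, , t] <- if (t %% 2) A else B
  mv <- dynamic_metric_variance(dgc, burn_in = 0, stride = 1)
  mA <- static_metrics(to_graph(A)); mB <- static_metrics(to_graph(B))
  expect_equal(mv$transitivity, ((mA$transitivity - mB$transitivity) / 2)^2,
               tolerance = 1e-12)
  expect_equal(mv$global_efficiency,
               ((mA$global_efficiency - mB$global_efficiency) / 2)^2,
               tolerance = 1e-12)
  expect_equal(unname(mv$cc), unname(((mA$cc - mB$cc) / 2)^2),
               tolerance = 1e-12)
  expect_equal(unname(mv$eb), unname(((mA$eb - mB$eb) / 2)^2),
               tolerance = 1e-12)
})

test_that("time-constant snapshots give zero variance everywhere", {
  k <- 4
  A <- random_digraph(k, seed = 800)
  dgc <- array(rep(A, 40), c(k, k, 40))
  mv <- dynamic_metric_variance(dgc, burn_in = 0)
  expect_equal(mv$transitivity, 0)
  expect_equal(max(mv$spl[is.finite(mv$spl)]), 0)
  expect_equal(max(mv$eb), 0)
})

test_that("stride subsampling approximates full-resolution variance", {
  set.seed(900)
  k <- 4
  Tt <- 200
  dgc <- array(0, c(k, k, Tt))
  base <- random_digraph(k, seed = 901)
  for (t in seq_len(Tt))
    dgc[, , t] <- base * (1 + 0.3 * sin(2 * pi * t / 50))
  v1 <- dynamic_metric_variance(dgc, burn_in = 0, stride = 1)
  v2 <- dynamic_metric_variance(dgc, burn_in = 0, stride = 2)
  expect_equal(v2$global_efficiency, v1$global_efficiency, tolerance = 0.1)
  expect_equal(v2$transitivity, v1$transitivity, tolerance = 0.1)
})
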