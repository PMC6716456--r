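test_that("comparison accounting follows the k + k(k-1) scheme", {
  expect_equal(unname(count_comparisons(2)), c(2L, 2L, 8L))
  expect_equal(unname(count_comparisons(20)), c(20L, 380L, 800L))
  expect_error(count_comparisons(1))
})

test_that("pairwise covariate-adjusted comparison behaves under null and shift", {
  set.seed(10)
  n <- 40
  g <- factor(rep(c("a", "b"), each = n / 2))
  cov <- data.frame(age = rnorm(n, 30, 5), education = rnorm(n, 14, 2),
                    race = sample(c("w", "b", "o"), n, TRUE),
                    motion = abs(rnorm(n, 0.1, 0.03)))
  # same data relabeled: no effect
  x <- rnorm(n)
  r <- ancova_pair(x, g, cov)
  expect_gt(r$p, 0.001)
  expect_lt(abs(diff(r$adjusted_means)), 1)
  # planted 3-sd shift: detected nearly always
  hits <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    y <- rnorm(n) + 3 * (g == "b")
    ancova_pair(y, g, cov)$p < 0.001
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("covariate-driven features give uniform group p-values", {
  ps <- vapply(1:200, function(s) {
    set.seed(2000 + s)
    n <- 40
    g <- factor(rep(c("a", "b"), each = n / 2))
    age <- rnorm(n, 30, 5)  # age-matched groups
    y <- 2 * age + rnorm(n)
    ancova_pair(y, g, data.frame(age = age), use = "age")$p
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("BH correction matches a naive oracle and honors the budget", {
  naive_bh <- function(p, q, m) {
    # step-up from the definition, O(m^2)
    o <- order(p)
    sig <- rep(FALSE, length(p))
    kmax <- 0
    for (i in seq_along(p))
      if (p[o[i]] <= i * q / m) kmax <- i
    if (kmax > 0) sig[o[seq_len(kmax)]] <- TRUE
    sig
  }
  for (s in 1:100) {
    set.seed(s)
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    m <- length(p) + sample(0:50, 1)
    expect_equal(fdr_bh(p, q = 0.05, m = m)$significant,
                 naive_bh(p, 0.05, m))
  }
  expect_true(fdr_bh(0.01, q = 0.05)$significant)
  expect_false(any(fdr_bh(rep(1, 5), q = 0.05)$significant))
  # q-values never fall below the raw p-values
  qq <- fdr_bh(runif(20), q = 0.05)
  expect_true(all(qq$q_values >= runif(0)))
})

test_that("trend conformance distinguishes monotone patterns and labels them", {
  expect_true(trend_filter(c(10, 7, 4), "var")$conforming)
  expect_equal(trend_filter(c(10, 7, 4), "var")$label, "rigidity")
  expect_false(trend_filter(c(10, 4, 7), "var")$conforming)
  up <- trend_filter(c(4, 7, 10), "static")
  expect_true(up$conforming)
  expect_equal(up$label, "inflation")
  expect_equal(trend_filter(c(10, 7, 4), "static")$label, "deflation")
  expect_false(trend_filter(c(4, 4, 10), "static")$conforming)  # tie breaks it
  # relaxed rule tolerates equal clinical groups
  expect_true(trend_filter(c(10, 4, 4), "static", relaxed = TRUE)$conforming)
  expect_false(trend_filter(c(4, 10, 2), "static", relaxed = TRUE)$conforming)
})

test_that("local-measure intersection is a plain set intersection", {
  expect_equal(intersect_local(c("a", "b"), c("c")), character(0))
  expect_equal(intersect_local(c("a", "b"), c("a", "b")), c("a", "b"))
  set.seed(3)
  for (r in 1:20) {
    a <- sample(letters, 8); b <- sample(letters, 8)
    expect_setequal(intersect_local(a, b), letters[letters %in% a & letters %in% b])
  }
})

test_that("hypothesis rules select planted units and gate on raw connectivity", {
  effects <- c(
    unit_effects("edge:A>B", h2_pattern),                  # full h2 + conn
    unit_effects("edge:B>C", h1_pattern),                  # h1 + conn h1
    unit_effects("edge:A>C", h2_pattern, conn = FALSE),    # h2 but no conn
    unit_effects("node:A", h2_pattern, measures = c("cc", "effloc"),
                 conn = FALSE),
    unit_effects("node:B", h2_pattern, measures = "cc", conn = FALSE))
  ft <- make_feature_table(effects = effects, seed = 5)
  hyp <- apply_hypotheses(ft$features, ft$manifest)
  expect_setequal(hyp$h2_edges, c("edge:A>B", "edge:A>C"))
  expect_equal(hyp$h1_edges, "edge:B>C")
  expect_setequal(hyp$gated_edges, c("edge:B>C", "edge:A>B"))
  expect_equal(hyp$h2_nodes, "node:A")   # node B fails the intersection
  expect_length(hyp$h1_nodes, 0)
  # h1 and h2 are mutually exclusive by construction
  expect_length(intersect(hyp$h1_edges, hyp$h2_edges), 0)
  u <- hyp$units
  expect_true(all(!(u$h1 & u$h2)))
  expect_equal(unname(hyp$budget["n_total"]), 18L)  # k = 3
})

test_that("selection is invariant to feature and subject order", {
  effects <- c(unit_effects("edge:A>B", h2_pattern),
               unit_effects("edge:B>C", h1_pattern))
  ft <- make_feature_table(effects = effects, seed = 6)
  hyp1 <- apply_hypotheses(ft$features, ft$manifest)
  set.seed(7)
  cp <- sample(ncol(ft$features))
  rp <- sample(nrow(ft$features))
  hyp2 <- apply_hypotheses(ft$features[rp, cp], ft$manifest[rp, ])
  expect_setequal(hyp2$h2_edges, hyp1$h2_edges)
  expect_setequal(hyp2$h1_edges, hyp1$h1_edges)
  expect_setequal(hyp2$gated_edges, hyp1$gated_edges)
})

test_that("null feature tables yield virtually no hypothesis-2 selections", {
  n_sel <- vapply(1:40, function(s) {
    ft <- make_feature_table(effects = list(), seed = 100 + s)
    hyp <- apply_hypotheses(ft$features, ft$manifest)
    length(hyp$h2_edges) + length(hyp$h2_nodes)
  }, 0)
  expect_lte(mean(n_sel > 0), 0.05)
})

test_that("edges without raw-connectivity support are dropped by the gate", {
  conn_units <- data.frame(measure = "conn",
                           scope = c("edge:A>B", "edge:B>C"),
                           h1 = c(FALSE, TRUE), h2 = c(FALSE, FALSE))
  gated <- connectivity_gate(list(h1 = c("edge:B>C", "edge:A>B"),
                                  h2 = c("edge:A>B")), conn_units)
  expect_equal(gated, "edge:B>C")
  expect_length(connectivity_gate(list(h1 = character(0), h2 = character(0)),
                                  conn_units), 0)
})
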