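test_that("behavior correlations are exact for identical vectors and control FWER", {
  set.seed(1)
  F <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, paste0("f", 1:3)))
  B <- cbind(PCL5 = F[, 1], NSI = rnorm(60))
  tab <- behavior_correlations(F, B)
  expect_equal(tab$r[tab$feature == "f1" & tab$behavior == "PCL5"], 1,
               tolerance = 1e-12)
  expect_equal(attr(tab, "n_tests"), 6)
  # family-wise error under the null
  fam_err <- vapply(1:100, function(s) {
    set.seed(300 + s)
    F0 <- matrix(rnorm(60 * 4), 60, 4)
    B0 <- matrix(rnorm(60 * 3), 60, 3)
    colnames(F0) <- paste0("f", 1:4); colnames(B0) <- paste0("b", 1:3)
    any(behavior_correlations(F0, B0)$significant)
  }, TRUE)
  expect_lte(mean(fam_err), 0.07)
})

test_that("planted negative feature-behavior link is recovered with its sign", {
  set.seed(2)
  n <- 50
  f <- rnorm(n)
  beh <- cbind(PCL5 = -0.7 * f + rnorm(n, sd = sqrt(1 - 0.49)))
  F <- cbind(v1 = f, v2 = rnorm(n))
  tab <- behavior_correlations(F, beh)
  hit <- tab[tab$feature == "v1", ]
  expect_lt(hit$r, -0.5)
  expect_true(hit$significant)
})

test_that("PLSR explains an exact rank-1 linear map and not independent noise", {
  set.seed(3)
  X <- matrix(rnorm(80 * 6), 80, 6)
  w <- rnorm(6); v <- c(1, -2, 0.5)
  Y <- (X %*% w) %*% t(v)           # rank-1, noise free
  fit <- plsr_assoc(X, Y, n_components = 2)
  expect_gt(fit$pct_variance_explained, 99)
  expect_gt(fit$latent_r2, 0.8)
  # independent blocks: small latent association
  Y0 <- matrix(rnorm(80 * 3), 80, 3)
  fit0 <- plsr_assoc(X, Y0, n_components = 2)
  expect_lt(fit0$pct_variance_explained, 30)
  expect_lt(fit0$latent_r2, 0.4)
})

test_that("PLSR agrees with an independent implementation on fitted Y variance", {
  skip_if_not_installed("mixOmics")
  set.seed(4)
  X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("x", 1:5)))
  Y <- X %*% matrix(rnorm(10), 5, 2) + matrix(rnorm(120, sd = 0.7), 60, 2)
  colnames(Y) <- c("y1", "y2")
  ours <- plsr_assoc(X, Y, n_components = 2)
  ref <- mixOmics::pls(X, Y, ncomp = 2, mode = "regression")
  pred <- predict(ref, X)$predict[, , 2]
  Ys <- scale(Y)
  preds <- sweep(sweep(pred, 2, attr(Ys, "scaled:center")), 2,
                 attr(Ys, "scaled:scale"), "/")
  ref_pct <- 100 * (1 - sum((Ys - preds)^2) / sum(Ys^2))
  expect_equal(ours$pct_variance_explained, ref_pct, tolerance = 5)
})

test_that("binomial significance matches direct summation", {
  expect_equal(binomial_significance(10, 10, 0.5), 0.5^10, tolerance = 1e-12)
  expect_gt(binomial_significance(5, 10, 0.5), 0.3)
  for (s in 1:20) {
    set.seed(s)
    n <- sample(5:60, 1)
    kk <- sample.int(n, 1)
    ch <- runif(1, 0.1, 0.9)
    direct <- sum(vapply(kk:n, function(i)
      choose(n, i) * ch^i * (1 - ch)^(n - i), 0))
    expect_equal(binomial_significance(kk, n, ch), direct, tolerance = 1e-12)
  }
})

test_that("RCE accounting, ordering, determinism and worst-case bound hold", {
  set.seed(5)
  X <- matrix(rnorm(36 * 12), 36, 12)
  y <- factor(rep(c("a", "b"), each = 18))
  X[y == "b", 1:2] <- X[y == "b", 1:2] + 4
  r1 <- rce_svm(X, y, reps = 3, folds = 3, clusters_init = 4,
                inner_folds = 2, seed = 11)
  expect_equal(r1$n_evaluations, 9)
  expect_true(all(diff(r1$steps$n_clusters) < 0))
  expect_equal(r1$steps$n_clusters[nrow(r1$steps)], 2)
  expect_true(all(r1$steps$min_accuracy <= r1$steps$mean_accuracy + 1e-12))
  r2 <- rce_svm(X, y, reps = 3, folds = 3, clusters_init = 4,
                inner_folds = 2, seed = 11)
  expect_identical(r1$steps, r2$steps)
  expect_identical(r1$feature_freq, r2$feature_freq)
})

test_that("test rows never influence RCE training-side decisions", {
  set.seed(6)
  X <- matrix(rnorm(30 * 10), 30, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- factor(rep(c("a", "b"), each = 15))
  X[y == "b", 1] <- X[y == "b", 1] + 3
  r1 <- rce_svm(X, y, reps = 1, folds = 2, clusters_init = 3,
                inner_folds = 2, seed = 21)
  # replace the first evaluation's held-out rows with junk; its training
  # fold is untouched, so its surviving feature set must not change
  te1 <- r1$fold_table[[1]]$test
  X2 <- X
  X2[te1, ] <- matrix(rnorm(length(te1) * 10, sd = 50), length(te1), 10)
  r2 <- rce_svm(X2, y, reps = 1, folds = 2, clusters_init = 3,
                inner_folds = 2, seed = 21)
  expect_identical(r2$fold_table[[1]]$test, te1)
  expect_identical(r2$fold_table[[1]]$surviving, r1$fold_table[[1]]$surviving)
})

test_that("SVR attains high R2 on a realizable target and low on noise", {
  set.seed(7)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- 2 * X[, 1] - X[, 2]
  fit <- svr_predict(X, y, iterations = 10, seed = 3)
  expect_gt(fit$mean_r2, 0.95)
  y0 <- rnorm(60)
  fit0 <- svr_predict(X, y0, iterations = 20, seed = 4)
  expect_lte(fit0$mean_r2, 0.05)
})
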