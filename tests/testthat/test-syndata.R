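test_that("VAR specification places planted edges and enforces stability", {
  spec <- make_var_spec(2, planted_chain = data.frame(from = 1, to = 2,
                                                      weight = 0.4),
                        self_coupling = 0.5)
  expect_equal(spec$A1[2, 1], 0.4)   # rows are targets
  expect_equal(diag(spec$A1), c(0.5, 0.5))
  expect_lt(spec$spectral_radius, 1)
  # zero multiplier leaves only the background
  spec0 <- make_var_spec(5, planted_chain = chain_edges(1:3, 0),
                         base_coupling = 0, self_coupling = 0.3)
  expect_equal(sum(abs(spec0$A1)) , 5 * 0.3)
  # determinism
  s1 <- make_var_spec(20, base_coupling = 0.05, seed = 9)
  s2 <- make_var_spec(20, base_coupling = 0.05, seed = 9)
  expect_identical(s1$A1, s2$A1)
  # instability rejected with a spectral-radius diagnostic
  expect_error(make_var_spec(2, self_coupling = 1.05), "spectral radius")
})

test_that("null VAR produces uncorrelated white noise", {
  spec <- make_var_spec(3, self_coupling = 0, base_coupling = 0)
  z <- simulate_neural(spec, T = 4000, seed = 5)
  ac <- apply(unclass(z), 2, function(x)
    cor(x[-1], x[-length(x)]))
  expect_true(all(abs(ac) < 3 / sqrt(4000)))
  cc <- cor(unclass(z))
  expect_true(all(abs(cc[upper.tri(cc)]) < 3 / sqrt(4000)))
})

test_that("OLS on simulated series recovers the planted lag-1 coefficient", {
  ts <- sim_coupled_pair(b = 0.4, T = 20000, seed = 2)
  z0 <- as.numeric(ts[, 1]); z1 <- as.numeric(ts[, 2])
  Tt <- length(z0)
  fit <- lm(z1[-1] ~ z0[-Tt] + z1[-Tt])
  expect_lt(abs(unname(coef(fit)[2]) - 0.4), 0.02)
})

test_that("scheduled step coupling is visible to windowed OLS", {
  spec <- make_var_spec(2, self_coupling = 0)
  sch <- schedule_step(1, 2, t_change = 1000, before = 0, after = 0.8)
  z <- simulate_neural(spec, T = 2000, schedule = sch, seed = 3)
  z0 <- as.numeric(z[, 1]); z1 <- as.numeric(z[, 2])
  co <- function(idx) {
    f <- lm(z1[idx] ~ z0[idx - 1] + z1[idx - 1])
    unname(coef(f)[2])
  }
  expect_lt(abs(co(2:900)), 0.1)
  expect_equal(co(1100:2000), 0.8, tolerance = 0.1)
})

test_that("double-gamma HRF peaks where requested", {
  h <- hrf_double_gamma(peak_time = 6, dt = 0.6, duration = 24)
  expect_gte(h$peak_time, 5.4)
  expect_lte(h$peak_time, 6.6)
  expect_equal(max(h$samples), 1)
  h0 <- hrf_double_gamma(ratio = 0, dt = 0.5)
  expect_true(all(h0$samples >= 0))
  # two curves with peaks 5 and 7 are cross-correlated at a 2 s lag
  h5 <- hrf_double_gamma(peak_time = 5, dt = 0.5, duration = 30)
  h7 <- hrf_double_gamma(peak_time = 7, dt = 0.5, duration = 30)
  cc <- ccf(h7$samples, h5$samples, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)] * 0.5, 2, tolerance = 0.51)
})

test_that("BOLD observation is an identity under a delta kernel and drowns under noise", {
  x <- roi_ts(matrix(rnorm(200), 100, 2), tr = 1)
  delta <- structure(list(samples = c(1, 0, 0), dt = 1, peak_time = 0),
                     class = "hrf")
  y <- convolve_bold(x, delta, obs_noise_sd = 0)
  expect_equal(unclass(y), unclass(x), ignore_attr = TRUE)
  # identical neural signals through 2 s-lagged HRFs peak-correlate at 2 s
  sc <- sim_lagged_hrf_pair(T = 600, tr = 1, peak_times = c(5, 7),
                            obs_noise_sd = 0, seed = 8)
  cc <- ccf(as.numeric(sc$bold[, 2]), as.numeric(sc$bold[, 1]),
            lag.max = 6, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 2)
  # heavy noise destroys inter-column correlation
  hb <- hrf_double_gamma(dt = 1)
  nn <- roi_ts(cbind(rnorm(400), rnorm(400)), tr = 1)
  yb <- convolve_bold(roi_ts(cbind(nn[, 1], nn[, 1]), tr = 1), hb,
                      obs_noise_sd = 500, seed = 2)
  expect_lt(abs(cor(yb[, 1], yb[, 2])), 0.2)
})

test_that("simulated cohorts are deterministic with planted monotone effects", {
  des <- cohort_design(n_per_group = c(4, 4, 4), k = 8, T = 120, TR = 1,
                       seed = 21)
  c1 <- simulate_cohort(des)
  c2 <- simulate_cohort(des)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$bold, c2$bold)
  gt <- c1$ground_truth$subjects
  ev <- gt[[grep("^edge_var", names(gt))[1]]]
  means <- tapply(ev, gt$group, mean)
  expect_true(means["control"] > means["ptsd"])
  expect_true(means["ptsd"] > means["pcs_ptsd"])
  # noise-free behavior reproduces the linear map exactly
  des0 <- cohort_design(n_per_group = c(3, 3, 3), k = 8, T = 120, TR = 1,
                        behavior_noise_sd = 0, seed = 22)
  c0 <- simulate_cohort(des0)
  B <- des0$behavior_loading
  gt0 <- c0$ground_truth$subjects
  expect_equal(c0$manifest$PCL5,
               as.numeric(B["PCL5", 1] + B["PCL5", 2] * gt0$strength_mult +
                            B["PCL5", 3] * gt0$variability_mult),
               tolerance = 1e-10)
})

test_that("cohort text round trip preserves series and manifest", {
  des <- cohort_design(n_per_group = c(2, 2, 2), k = 6, T = 80, TR = 1,
                       seed = 31)
  coh <- simulate_cohort(des)
  dir <- tempfile("cohort")
  write_cohort(coh, dir)
  ts <- read_roi_ts(file.path(dir, "S001.tsv"), tr = 1)
  expect_equal(unclass(ts), unclass(coh$bold$S001), tolerance = 1e-10,
               ignore_attr = TRUE)
  man <- read.delim(file.path(dir, "manifest.tsv"))
  expect_equal(man$PCL5, coh$manifest$PCL5, tolerance = 1e-10)
})
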