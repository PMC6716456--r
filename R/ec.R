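#' Fit a zero-lag-augmented multivariate autoregressive model
#'
#' Fits, per target region j, the model
#' `z_j(t) = sum_{i != j} m0_ij z_i(t) + sum_n sum_i m_ij(n) z_i(t-n) + e_j(t)`
#' by least squares: the zero-lag term `M(0)` (zero diagonal) absorbs
#' instantaneous cross-correlation so that it does not leak into the
#' lagged, directional coefficients. Columns are standardized (zero mean,
#' unit variance) before fitting so coefficients are comparable across
#' subjects.
#'
#' @param ts [roi_ts()] or numeric matrix, T x k, `T > 10 * k * (p + 1)`.
#' @param p model order (lags); the pipeline default is 1.
#' @return `mvar_fit` list: `M0` (k x k, zero diagonal), `M` (list of p
#'   k x k lag matrices, `M[[n]][i, j]` = coefficient of region i at lag n
#'   in the model of region j), `residuals` ((T - p) x k), `p`.
#' @export
fit_mvar <- function(ts, p = 1L) {
  Z <- standardize_ts(as.matrix(ts))
  Tn <- nrow(Z); k <- ncol(Z)
  if (Tn <= 10 * k * (p + 1))
    stop("too few timepoints: need T > 10 * k * (p + 1)")
  rows <- (p + 1L):Tn
  lagged <- lapply(seq_len(p), function(n) Z[rows - n, , drop = FALSE])
  M0 <- matrix(0, k, k, dimnames = list(colnames(Z), colnames(Z)))
  M <- lapply(seq_len(p), function(n) M0)
  resid <- matrix(0, length(rows), k)
  for (j in seq_len(k)) {
    X <- cbind(Z[rows, -j, drop = FALSE], do.call(cbind, lagged))
    q <- qr(X)
    if (q$rank < ncol(X)) {
      cols <- c(paste0("zl:", colnames(Z)[-j]),
                unlist(lapply(seq_len(p), function(n)
                  paste0("lag", n, ":", colnames(Z)))))
      stop(sprintf("rank-deficient predictors for target %s (involving %s)",
                   colnames(Z)[j],
                   paste(cols[q$pivot[(q$rank + 1L):ncol(X)]], collapse = ", ")))
    }
    b <- qr.coef(q, Z[rows, j])
    M0[-j, j] <- b[seq_len(k - 1L)]
    for (n in seq_len(p))
      M[[n]][, j] <- b[(k - 1L) + (n - 1L) * k + seq_len(k)]
    resid[, j] <- qr.resid(q, Z[rows, j])
  }
  structure(list(M0 = M0, M = M, residuals = resid, p = p),
            class = "mvar_fit")
}

#' Static Granger causality from fitted MVAR coefficients
#'
#' `gc[i, j] = sum_{n = 1..p} m_ij(n)`: the total lagged influence of
#' region i on region j. The zero-lag matrix `M(0)` models covariance only
#' and is excluded; the diagonal (self-prediction) is zeroed. Sign is
#' retained here — absolute values are taken only at graph construction.
#'
#' @param fit an [fit_mvar()] result.
#' @return `sec_matrix`: k x k matrix of signed GC values, zero diagonal.
#' @export
static_gc <- function(fit) {
  stopifnot(inherits(fit, "mvar_fit"))
  gc <- Reduce(`+`, fit$M)
  diag(gc) <- 0
  structure(gc, class = c("sec_matrix", "matrix", "array"))
}

#' Kalman-filter estimation of a dynamic MVAR model
#'
#' Time-varying counterpart of [fit_mvar()]: the same per-target
#' regression (zero-lag others + all regions at lags 1..p) estimated
#' recursively by a Kalman filter / recursive-least-squares scheme with a
#' forgetting factor. Forgetting 1 keeps all history (the recursion
#' converges to the batch least-squares fit); forgetting just below 1
#' discounts the past exponentially, letting coefficients track genuine
#' temporal change.
#'
#' @param ts [roi_ts()] or matrix; columns are standardized internally.
#' @param p model order.
#' @param forgetting forgetting factor in (0.9, 1].
#' @param state_cov_init initial state covariance scale (kappa * I).
#' @return `dmvar_fit` list: `M0t` (k x k x T array, zero diagonal at all
#'   t), `Mt` (list over lags of k x k x T arrays), `p`, `forgetting`,
#'   `pe_var` (per-target recursive prediction-error variance). Entries at
#'   t <= p repeat the first estimated timepoint.
#' @export
kalman_dmvar <- function(ts, p = 1L, forgetting = 1.0, state_cov_init = 1.0) {
  if (!(forgetting > 0.9 && forgetting <= 1))
    stop("forgetting must lie in (0.9, 1]")
  Z <- standardize_ts(as.matrix(ts))
  Tn <- nrow(Z); k <- ncol(Z)
  if (Tn <= 10 * k * (p + 1))
    stop("too few timepoints: need T > 10 * k * (p + 1)")
  rows <- (p + 1L):Tn
  lagged <- do.call(cbind, lapply(seq_len(p), function(n)
    Z[rows - n, , drop = FALSE]))
  dn <- list(colnames(Z), colnames(Z), NULL)
  M0t <- array(0, c(k, k, Tn), dimnames = dn)
  Mt <- lapply(seq_len(p), function(n) M0t)
  pe_var <- numeric(k)
  for (j in seq_len(k)) {
    Phi <- cbind(Z[rows, -j, drop = FALSE], lagged)
    res <- .kalman_rls_cpp(Phi, Z[rows, j], forgetting, state_cov_init)
    co <- res$coef  # (Tn - p) x m trajectory
    pe_var[j] <- res$pe_var
    M0t[-j, j, rows] <- t(co[, seq_len(k - 1L), drop = FALSE])
    for (n in seq_len(p))
      Mt[[n]][, j, rows] <- t(co[, (k - 1L) + (n - 1L) * k + seq_len(k),
                                 drop = FALSE])
    # backfill the first p timepoints with the first estimate
    for (t0 in seq_len(p)) {
      M0t[, j, t0] <- M0t[, j, p + 1L]
      for (n in seq_len(p)) Mt[[n]][, j, t0] <- Mt[[n]][, j, p + 1L]
    }
  }
  structure(list(M0t = M0t, Mt = Mt, p = p, forgetting = forgetting,
                 state_cov_init = state_cov_init, pe_var = pe_var),
            class = "dmvar_fit")
}

#' Dynamic Granger causality series from a dynamic MVAR fit
#'
#' `dgc[i, j, t] = sum_{n = 1..p} m_ij(n, t)`: the time-resolved lagged
#' influence of region i on region j. Diagonal is zero at every t.
#'
#' @param fit_dyn a [kalman_dmvar()] result.
#' @return `dec_series` list: `dgc` (k x k x T array), `p`, `forgetting`.
#' @export
dynamic_gc <- function(fit_dyn) {
  stopifnot(inherits(fit_dyn, "dmvar_fit"))
  dgc <- Reduce(`+`, fit_dyn$Mt)
  k <- dim(dgc)[1]
  for (i in seq_len(k)) dgc[i, i, ] <- 0
  structure(list(dgc = dgc, p = fit_dyn$p, forgetting = fit_dyn$forgetting),
            class = "dec_series")
}

#' Default burn-in for dynamic connectivity series
#'
#' The Kalman recursion needs a transient to move away from its zero
#' initialization; the first `max(50, 5% of T)` timepoints are excluded
#' from variability summaries by default.
#'
#' @param T number of timepoints.
#' @export
default_burn_in <- function(T) max(50L, ceiling(0.05 * T))

#' Edge-wise temporal variance of dynamic connectivity
#'
#' Population variance of `dgc[i, j, t]` over retained timepoints
#' `t > burn_in` — the "variability of effective connectivity" feature.
#'
#' @param dec a [dynamic_gc()] result (or k x k x T array).
#' @param burn_in discarded prefix length; must be < T/2.
#' @return `ec_variance`: k x k matrix of variances (zero diagonal), with
#'   attribute `burn_in`.
#' @export
dec_variance <- function(dec, burn_in = NULL) {
  dgc <- if (inherits(dec, "dec_series")) dec$dgc else dec
  Tn <- dim(dgc)[3]
  if (is.null(burn_in)) burn_in <- default_burn_in(Tn)
  if (burn_in >= Tn / 2) stop("burn_in must be below T/2")
  keep <- (burn_in + 1L):Tn
  m <- apply(dgc[, , keep, drop = FALSE], c(1, 2), pop_var)
  diag(m) <- 0
  attr(m, "burn_in") <- burn_in
  class(m) <- c("ec_variance", "matrix", "array")
  m
}

# population variance (divide by N): the descriptive temporal moment used
# for all variability features; exact for periodic trajectories
pop_var <- function(x) {
  mean((x - mean(x))^2)
}

#' One-call static and dynamic connectivity for one subject
#'
#' Convenience wrapper: standardizes, fits the static MVAR and the
#' dynamic (Kalman) MVAR, and returns the signed SEC matrix, the DGC
#' tensor and its temporal variance.
#'
#' @inheritParams kalman_dmvar
#' @param burn_in burn-in for [dec_variance()] (default
#'   [default_burn_in()]).
#' @return list `sec`, `dec`, `vdec`.
#' @export
connectivity <- function(ts, p = 1L, forgetting = 1.0, state_cov_init = 1.0,
                         burn_in = NULL) {
  sec <- static_gc(fit_mvar(ts, p = p))
  dec <- dynamic_gc(kalman_dmvar(ts, p = p, forgetting = forgetting,
                                 state_cov_init = state_cov_init))
  vdec <- dec_variance(dec, burn_in = burn_in)
  list(sec = sec, dec = dec, vdec = vdec)
}
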