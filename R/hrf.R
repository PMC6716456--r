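#' Double-gamma hemodynamic response function
#'
#' Canonical double-gamma HRF: a gamma-density response peaking at
#' `peak_time` minus a scaled gamma-density undershoot peaking at
#' `undershoot_time`, sampled every `dt` seconds over `duration` seconds
#' and normalized so the peak amplitude is 1. Region-specific HRFs with
#' jittered peak times realize the spatial variability of neurovascular
#' coupling that confounds directional connectivity estimated on raw BOLD.
#'
#' @param peak_time time-to-peak in seconds.
#' @param undershoot_time time of undershoot minimum in seconds.
#' @param ratio undershoot amplitude relative to the response (0 = none).
#' @param dt sampling interval in seconds.
#' @param duration total support in seconds.
#' @return An `hrf` object: list with `samples`, `dt`, `peak_time`.
#' @examples
#' h <- hrf_double_gamma(peak_time = 6, dt = 2)
#' which.max(h$samples)  # peak near 6 s
#' @export
hrf_double_gamma <- function(peak_time = 6, undershoot_time = 16,
                             ratio = 1 / 6, dt = 1, duration = 24) {
  stopifnot(dt > 0, dt <= peak_time, peak_time < duration, ratio >= 0)
  t <- seq(0, duration, by = dt)
  # gamma density with rate 1 has its mode at shape - 1
  h <- dgamma(t, shape = peak_time + 1, rate = 1) -
    ratio * dgamma(t, shape = undershoot_time + 1, rate = 1)
  h <- h / max(h)
  structure(list(samples = h, dt = dt, peak_time = t[which.max(h)]),
            class = "hrf")
}

#' @export
print.hrf <- function(x, ...) {
  cat(sprintf("HRF: %d samples at dt = %g s, peak at %g s\n",
              length(x$samples), x$dt, x$peak_time))
  invisible(x)
}

#' Observe latent neural signals through region-specific HRFs
#'
#' Causally convolves each region's latent neural signal with that
#' region's HRF and adds white observation noise, producing BOLD-like
#' time series. The convolution tail beyond T is truncated (output keeps
#' the input length); each HRF must be sampled at the series TR.
#'
#' @param neural [roi_ts()] of latent signals.
#' @param hrfs a single `hrf` (recycled) or a list of one `hrf` per region.
#' @param obs_noise_sd observation noise standard deviation.
#' @param seed integer seed for the noise draw.
#' @return [roi_ts()] of the same dimension as `neural`.
#' @export
convolve_bold <- function(neural, hrfs, obs_noise_sd = 0, seed = 1L) {
  tr <- roi_tr(neural)
  k <- ncol(neural)
  if (inherits(hrfs, "hrf")) hrfs <- rep(list(hrfs), k)
  stopifnot(length(hrfs) == k)
  Tn <- nrow(neural)
  out <- matrix(0, Tn, k)
  for (j in seq_len(k)) {
    h <- hrfs[[j]]
    if (abs(h$dt - tr) > 1e-9)
      stop(sprintf("HRF for region %d sampled at dt = %g, but series TR = %g",
                   j, h$dt, tr))
    # causal FIR: y[t] = sum_l h[l] * x[t - l]
    y <- stats::filter(c(rep(0, length(h$samples) - 1L), neural[, j]),
                       filter = h$samples, method = "convolution",
                       sides = 1L)
    out[, j] <- as.numeric(y)[length(h$samples) - 1L + seq_len(Tn)]
  }
  if (obs_noise_sd > 0) {
    set.seed(seed)
    out <- out + matrix(rnorm(Tn * k, sd = obs_noise_sd), Tn, k)
  }
  roi_ts(out, tr = tr, labels = colnames(neural))
}
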