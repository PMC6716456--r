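#' Construct a stable first-order VAR specification with a planted chain
#'
#' Builds the generative side of the connectivity model: a latent neural
#' system `Z(t) = A0 Z(t) + A1 Z(t-1) + E(t)` with zero-diagonal
#' instantaneous coupling `A0` and lag-1 coupling `A1`. Directed edges of
#' the planted chain are written into `A1` at their stated magnitudes; all
#' remaining off-diagonal entries receive small Gaussian background
#' coupling so estimated networks are dense, as real effective-connectivity
#' matrices are.
#'
#' @param k number of regions (nodes), `k >= 2`.
#' @param planted_chain data.frame with columns `from`, `to` (1-based node
#'   indices) and `weight` (lag-1 coefficient), or `NULL` for none.
#' @param base_coupling standard deviation of the background off-diagonal
#'   lag-1 coupling (0 gives an exactly sparse system).
#' @param self_coupling common diagonal of `A1` (lag-1 autocorrelation of
#'   each region).
#' @param a0 optional k x k instantaneous coupling matrix (diagonal forced
#'   to zero); default none.
#' @param noise_sd innovation standard deviation, scalar or length-k.
#' @param seed integer seed for the background draw.
#' @return A `var_spec` list with elements `k`, `A0`, `A1`, `noise_sd`.
#' @examples
#' spec <- make_var_spec(5, planted_chain = chain_edges(1:3, 0.4), seed = 1)
#' spec$A1[1, 2]
#' @export
make_var_spec <- function(k, planted_chain = NULL, base_coupling = 0,
                          self_coupling = 0.3, a0 = NULL, noise_sd = 1,
                          seed = 1L) {
  stopifnot(k >= 2)
  A1 <- matrix(0, k, k)
  if (base_coupling > 0) {
    set.seed(seed)
    A1[] <- rnorm(k * k, sd = base_coupling)
  }
  diag(A1) <- self_coupling
  if (!is.null(planted_chain)) {
    stopifnot(all(c("from", "to", "weight") %in% names(planted_chain)))
    if (any(abs(planted_chain$weight) >= 1))
      stop("planted coupling magnitudes must be < 1")
    # A1 rows are targets, columns sources: edge from -> to sits at [to, from]
    for (r in seq_len(nrow(planted_chain)))
      A1[planted_chain$to[r], planted_chain$from[r]] <- planted_chain$weight[r]
  }
  if (is.null(a0)) a0 <- matrix(0, k, k)
  a0 <- as.matrix(a0)
  stopifnot(all(dim(a0) == c(k, k)))
  diag(a0) <- 0
  rho <- max(Mod(eigen(A1, only.values = TRUE)$values))
  if (rho >= 1)
    stop(sprintf("unstable VAR specification: spectral radius of A1 is %.4f (>= 1)",
                 rho))
  structure(list(k = k, A0 = a0, A1 = A1,
                 noise_sd = rep_len(noise_sd, k),
                 spectral_radius = rho),
            class = "var_spec")
}

#' Helper: edges along an ordered node chain
#'
#' @param nodes ordered vector of node indices; consecutive pairs become
#'   directed edges.
#' @param weight single coupling weight applied to every chain edge, or one
#'   weight per edge.
#' @return data.frame with columns `from`, `to`, `weight`.
#' @export
chain_edges <- function(nodes, weight) {
  n <- length(nodes) - 1L
  data.frame(from = nodes[seq_len(n)], to = nodes[seq_len(n) + 1L],
             weight = rep_len(weight, n))
}

#' Time-varying coupling schedules
#'
#' A schedule assigns a trajectory to selected lag-1 edges, making the
#' generative model dynamic: `A1(t)` equals the static `A1` with scheduled
#' entries replaced by their trajectory value at time `t`.
#' `schedule_step` switches an edge between two values at a changepoint;
#' `schedule_sine` modulates an edge sinusoidally about a center value.
#'
#' @param from,to 1-based node indices of the scheduled edge.
#' @param t_change time index (1-based) at which the step occurs.
#' @param before,after coefficient value before / from `t_change` on.
#' @param center,amplitude,period,phase sinusoid `center + amplitude *
#'   sin(2*pi*t/period + phase)`.
#' @return A one-edge schedule (list); concatenate schedules with `c()`.
#' @export
schedule_step <- function(from, to, t_change, before, after) {
  structure(list(list(from = from, to = to,
                      value = function(t) ifelse(t < t_change, before, after),
                      bounds = range(before, after))),
            class = "dyn_schedule")
}

#' @rdname schedule_step
#' @export
schedule_sine <- function(from, to, center, amplitude, period, phase = 0) {
  force(center); force(amplitude); force(period); force(phase)
  structure(list(list(from = from, to = to,
                      value = function(t)
                        center + amplitude * sin(2 * pi * t / period + phase),
                      bounds = c(center - abs(amplitude), center + abs(amplitude)))),
            class = "dyn_schedule")
}

#' @export
c.dyn_schedule <- function(...) {
  structure(do.call("c", lapply(list(...), unclass)), class = "dyn_schedule")
}

# A1 with scheduled edges evaluated at extreme bound values must stay stable
check_schedule_stability <- function(spec, schedule) {
  if (is.null(schedule) || length(schedule) == 0L) return(invisible(TRUE))
  # worst case over the corner combinations of each edge's bounds (edges are
  # few; 2^n corners with n = scheduled edge count, capped for safety)
  bnds <- lapply(schedule, `[[`, "bounds")
  n <- length(schedule)
  if (n > 12L) stop("too many scheduled edges to verify stability")
  for (mask in 0:(2^n - 1L)) {
    A <- spec$A1
    for (e in seq_len(n)) {
      v <- bnds[[e]][1L + bitwAnd(bitwShiftR(mask, e - 1L), 1L)]
      A[schedule[[e]]$to, schedule[[e]]$from] <- v
    }
    rho <- max(Mod(eigen(A, only.values = TRUE)$values))
    if (rho >= 1)
      stop(sprintf("schedule leaves the model unstable (spectral radius %.4f at a bound combination)", rho))
  }
  invisible(TRUE)
}

#' Simulate latent neural signals from a (time-varying) VAR process
#'
#' Iterates `Z(t) = A0 Z(t) + A1(t) Z(t-1) + E(t)`, i.e.
#' `Z(t) = (I - A0)^{-1} (A1(t) Z(t-1) + E(t))`, with `A1(t)` taken from
#' the schedule (constant `A1` when the schedule is empty). A warmup
#' stretch (100 samples, simulated at the t = 1 coefficients) is discarded
#' so the returned segment starts near stationarity.
#'
#' @param spec a [make_var_spec()] object.
#' @param T number of timepoints to return; must satisfy `T >= 10 * k`.
#' @param schedule a schedule from [schedule_step()] / [schedule_sine()],
#'   or `NULL`.
#' @param tr repetition time attached to the output (seconds).
#' @param seed integer seed.
#' @return [roi_ts()] of dimension T x k.
#' @export
simulate_neural <- function(spec, T, schedule = NULL, tr = 2, seed = 1L) {
  stopifnot(inherits(spec, "var_spec"))
  if (T < 10 * spec$k)
    stop("T must be at least 10 * k for a usable simulation")
  check_schedule_stability(spec, schedule)
  k <- spec$k
  set.seed(seed)
  warm <- 100L
  Ainv <- solve(diag(k) - spec$A0)
  E <- matrix(rnorm((T + warm) * k), T + warm, k) *
    matrix(spec$noise_sd, T + warm, k, byrow = TRUE)
  Z <- matrix(0, T + warm, k)
  A1t <- spec$A1
  sched_const <- is.null(schedule) || length(schedule) == 0L
  z_prev <- rnorm(k) * spec$noise_sd
  for (t in seq_len(T + warm)) {
    if (!sched_const) {
      tt <- max(1L, t - warm)  # warmup runs at the t = 1 coefficients
      for (e in schedule)
        A1t[e$to, e$from] <- e$value(tt)
    }
    z <- Ainv %*% (A1t %*% z_prev + E[t, ])
    if (any(abs(z) > 1e6))
      stop(sprintf("simulation diverged at t = %d (|Z| exceeded 1e6)",
                   t - warm))
    Z[t, ] <- z
    z_prev <- z
  }
  roi_ts(Z[warm + seq_len(T), , drop = FALSE], tr = tr)
}
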