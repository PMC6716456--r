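#' Cohort design for synthetic three-group studies
#'
#' Describes a synthetic cohort with three groups (`control`, `ptsd`,
#' `pcs_ptsd`) whose latent directional coupling differs in strength and
#' in temporal variability along a planted chain of regions, emulating the
#' hypothesized control -> PTSD -> PCS+PTSD gradient: coupling strength
#' changes monotonically across groups (inflation or deflation) while
#' coupling variability decreases (rigidity). Behavioral scores (PCL5,
#' NSI, NCI) are linear functions of each subject's generative multipliers
#' plus noise, so feature-behavior associations have known sign.
#'
#' Defaults describe the full-scale study the pipeline targets (87
#' subjects in three groups, 125 regions, 1000 timepoints); analyses in
#' the vignette and tests pass reduced sizes explicitly.
#'
#' @param n_per_group integer vector of 3 group sizes (control, ptsd,
#'   pcs_ptsd).
#' @param k,T,TR regions, timepoints, repetition time (seconds).
#' @param planted_chain data.frame `from`, `to`, `weight`: the base lag-1
#'   coupling of the planted directional chain. Default: a 5-node
#'   prefrontal -> insula -> amygdala -> hippocampus -> precuneus-like
#'   chain over the first 5 regions at weight 0.35.
#' @param strength_mult per-group multipliers on planted edge weights;
#'   must be monotone across groups.
#' @param variability_mult per-group multipliers on the temporal coupling
#'   oscillation amplitude; must be strictly decreasing (rigidity).
#' @param base_amplitude oscillation amplitude of planted edges before the
#'   group multiplier (coupling varies sinusoidally about its weight).
#' @param oscillation_period range (in timepoints) of the per-edge
#'   coupling-oscillation period.
#' @param anchor_edges data.frame `from`, `to`, `weight`: group-invariant
#'   connections (most real connections do not differ between groups).
#'   The default builds a routing context around the chain: a strong
#'   anchor pair that fixes the weight normalization, feeder inputs into
#'   the chain head, distributor outputs from the chain tail, and a
#'   staggered family of weak shortcuts competing with the chain for
#'   shortest-path routing, so integration measures respond gradually to
#'   chain strength.
#' @param base_coupling background coupling sd between unplanted region
#'   pairs.
#' @param subject_jitter_sd sd of per-subject jitter added to the group
#'   multipliers.
#' @param hrf_peak_range range of the uniform per-region time-to-peak
#'   jitter (seconds).
#' @param obs_noise_sd BOLD observation noise sd.
#' @param behavior_loading 3 x 3 matrix: rows PCL5, NSI, NCI; columns
#'   (intercept, strength multiplier, variability multiplier).
#' @param behavior_noise_sd sd of behavioral score noise (length 3 or 1).
#' @param seed integer master seed.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_per_group = c(29L, 29L, 29L),
                          k = 125L, T = 1000L, TR = 2,
                          planted_chain = NULL,
                          strength_mult = c(1.0, 0.72, 0.56),
                          variability_mult = c(1.0, 0.6, 0.12),
                          base_amplitude = 0.45,
                          oscillation_period = c(280, 420),
                          anchor_edges = NULL,
                          base_coupling = 0.02,
                          subject_jitter_sd = 0.06,
                          hrf_peak_range = c(4.5, 7.5),
                          obs_noise_sd = 0.2,
                          behavior_loading = rbind(
                            PCL5 = c(62, -30, -20),
                            NSI  = c(47, -25, -15),
                            NCI  = c(80, 25, 10)),
                          behavior_noise_sd = 5,
                          seed = 1L) {
  stopifnot(length(n_per_group) == 3L, all(n_per_group >= 1L), k >= 5L)
  if (is.null(planted_chain)) {
    labels <- c("PFC", "INS", "AMY", "HIP", "PCU")
    planted_chain <- chain_edges(1:5, 0.55)
  } else labels <- NULL
  if (is.null(anchor_edges)) {
    # group-invariant context: a strong anchor pair (fixes the weight
    # normalization), feeder inputs into the chain head, distributor
    # outputs from the chain tail, and a staggered family of weak direct
    # shortcuts that compete with the chain for routing (gives the
    # integration measures a graded response to chain strength)
    nmax <- max(planted_chain$from, planted_chain$to)
    first <- planted_chain$from[1]
    last <- planted_chain$to[nrow(planted_chain)]
    anchor_edges <- NULL
    if (nmax + 2L <= k)
      anchor_edges <- data.frame(from = nmax + 1L, to = nmax + 2L,
                                 weight = 0.75)
    if (nmax + 12L <= k) {
      feeders <- nmax + (3:7)
      dists <- nmax + (8:12)
      ws <- 0.08 + 0.015 * (0:4)
      anchor_edges <- rbind(
        anchor_edges,
        data.frame(from = feeders, to = first, weight = 0.3),
        data.frame(from = last, to = dists, weight = 0.3),
        data.frame(from = feeders, to = last, weight = ws),
        data.frame(from = first, to = dists, weight = rev(ws)))
    }
  }
  d <- diff(strength_mult)
  if (!(all(d > 0) || all(d < 0)))
    stop("strength_mult must be strictly monotone across control -> ptsd -> pcs_ptsd")
  if (!all(diff(variability_mult) < 0))
    stop("variability_mult must be strictly decreasing across groups (rigidity)")
  structure(list(n_per_group = as.integer(n_per_group), k = as.integer(k),
                 T = as.integer(T), TR = TR, planted_chain = planted_chain,
                 chain_labels = labels, strength_mult = strength_mult,
                 variability_mult = variability_mult,
                 base_amplitude = base_amplitude,
                 oscillation_period = oscillation_period,
                 anchor_edges = anchor_edges,
                 base_coupling = base_coupling,
                 subject_jitter_sd = subject_jitter_sd,
                 hrf_peak_range = hrf_peak_range,
                 obs_noise_sd = obs_noise_sd,
                 behavior_loading = behavior_loading,
                 behavior_noise_sd = rep_len(behavior_noise_sd, 3L),
                 seed = as.integer(seed)),
            class = "cohort_design")
}

group_levels <- c("control", "ptsd", "pcs_ptsd")

#' Simulate a synthetic cohort with planted group effects
#'
#' For every subject: builds a stable VAR specification whose planted
#' chain edges carry the subject's strength multiplier, schedules a
#' sinusoidal coupling oscillation whose amplitude carries the subject's
#' variability multiplier, simulates latent neural signals, observes them
#' through per-region jittered double-gamma HRFs with additive noise, and
#' draws covariates and behavioral scores. A ground-truth annex records
#' the planted edges and every subject's generative multipliers and
#' scheduled-coupling variance.
#'
#' @param design a [cohort_design()].
#' @param keep_latent keep the latent neural series alongside the BOLD
#'   series (memory permitting).
#' @return A `cohort` list: `bold` (named list of [roi_ts()]), `manifest`
#'   (data.frame: subject, group, age, education, race, motion, PCL5,
#'   NSI, NCI), `ground_truth` (list: `chain`, `group_multipliers`,
#'   `subjects` data.frame with per-subject multipliers and per-edge
#'   scheduled variance), and optionally `latent`.
#' @export
simulate_cohort <- function(design, keep_latent = FALSE) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  n <- sum(design$n_per_group)
  group <- factor(rep(group_levels, design$n_per_group),
                  levels = group_levels)
  ids <- sprintf("S%03d", seq_len(n))
  chain <- design$planted_chain
  ne <- nrow(chain)

  # covariates: same distributions in every group (no confounding planted)
  age <- round(rnorm(n, 32, 8))
  age <- pmin(pmax(age, 19), 55)
  education <- round(rnorm(n, 14, 2))
  race <- sample(c("white", "black", "hispanic", "other"), n, replace = TRUE,
                 prob = c(0.55, 0.2, 0.15, 0.1))
  motion <- abs(rnorm(n, 0.12, 0.04))

  gidx <- as.integer(group)
  s_mult <- design$strength_mult[gidx] + rnorm(n, 0, design$subject_jitter_sd)
  v_mult <- pmax(0.05, design$variability_mult[gidx] +
                   rnorm(n, 0, design$subject_jitter_sd))

  B <- design$behavior_loading
  X <- cbind(1, s_mult, v_mult)
  beh <- X %*% t(B) +
    matrix(rnorm(n * 3), n, 3) %*% diag(design$behavior_noise_sd)
  colnames(beh) <- rownames(B)

  bold <- vector("list", n)
  latent <- if (keep_latent) vector("list", n) else NULL
  names(bold) <- ids
  edge_var <- matrix(0, n, ne)  # generative variance of scheduled coupling
  subj_seeds <- sample.int(2^31 - 2, 3L * n)

  labels <- paste0("R", seq_len(design$k))
  if (!is.null(design$chain_labels))
    labels[seq_along(design$chain_labels)] <- design$chain_labels

  for (i in seq_len(n)) {
    ch <- chain
    ch$weight <- ch$weight * s_mult[i]
    # amplitude capped so scheduled coupling stays clear of zero (distance
    # features are 1/|weight|; couplings through zero would give unbounded
    # snapshot distances)
    amp <- design$base_amplitude * v_mult[i]
    amp <- min(amp, max(0.05, min(abs(ch$weight)) - 0.1))
    periods <- runif(ne, design$oscillation_period[1],
                     design$oscillation_period[2])
    phases <- runif(ne, 0, 2 * pi)
    spec <- NULL
    for (attempt in 1:5) {
      planted <- if (is.null(design$anchor_edges)) ch else
        rbind(ch, design$anchor_edges)
      spec <- tryCatch(
        make_var_spec(design$k, planted_chain = planted,
                      base_coupling = design$base_coupling,
                      seed = subj_seeds[i] + attempt - 1L),
        error = function(e) NULL)
      if (!is.null(spec)) {
        sched <- NULL
        for (e in seq_len(ne)) {
          s1 <- schedule_sine(ch$from[e], ch$to[e], center = ch$weight[e],
                              amplitude = amp, period = periods[e],
                              phase = phases[e])
          sched <- if (is.null(sched)) s1 else c(sched, s1)
        }
        ok <- tryCatch({check_schedule_stability(spec, sched); TRUE},
                       error = function(e) FALSE)
        if (ok) break
        spec <- NULL
      }
      ch$weight <- ch$weight * 0.97  # jitter toward stability and retry
      if (attempt == 5L)
        stop(sprintf("could not build a stable specification for subject %s",
                     ids[i]))
    }
    neu <- simulate_neural(spec, T = design$T, schedule = sched,
                           tr = design$TR, seed = subj_seeds[n + i])
    colnames(neu) <- labels
    set.seed(subj_seeds[2L * n + i])
    hrfs <- lapply(seq_len(design$k), function(j)
      hrf_double_gamma(peak_time = runif(1, design$hrf_peak_range[1],
                                         design$hrf_peak_range[2]),
                       dt = design$TR))
    bold[[i]] <- convolve_bold(neu, hrfs, obs_noise_sd = design$obs_noise_sd,
                               seed = subj_seeds[2L * n + i])
    if (keep_latent) latent[[i]] <- neu
    edge_var[i, ] <- amp^2 / 2  # variance of a sinusoid of amplitude amp
  }

  manifest <- data.frame(subject = ids, group = group, age = age,
                         education = education, race = race, motion = motion,
                         PCL5 = beh[, "PCL5"], NSI = beh[, "NSI"],
                         NCI = beh[, "NCI"], stringsAsFactors = FALSE)
  gt_subjects <- data.frame(subject = ids, group = group,
                            strength_mult = s_mult, variability_mult = v_mult)
  for (e in seq_len(ne))
    gt_subjects[[sprintf("edge_var_%d_%d", chain$from[e], chain$to[e])]] <-
      edge_var[, e]
  gt_chain <- chain
  gt_chain$from_label <- labels[chain$from]
  gt_chain$to_label <- labels[chain$to]
  out <- list(bold = bold, manifest = manifest,
              ground_truth = list(
                chain = gt_chain,
                group_multipliers = data.frame(
                  group = group_levels,
                  strength_mult = design$strength_mult,
                  variability_mult = design$variability_mult),
                subjects = gt_subjects),
              design = design)
  if (keep_latent) out$latent <- latent
  class(out) <- "cohort"
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%s), %d regions, %d timepoints\n",
              nrow(x$manifest),
              paste(table(x$manifest$group), collapse = "/"),
              x$design$k, x$design$T))
  invisible(x)
}

#' Write a cohort to delimited-text files
#'
#' One TSV per subject (T rows x k labeled columns), `manifest.tsv`, and
#' the ground-truth annex as two TSV tables (`ground_truth_chain.tsv`,
#' `ground_truth_subjects.tsv`).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$bold))
    write_roi_ts(cohort$bold[[id]], file.path(dir, paste0(id, ".tsv")))
  write.table(cohort$manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$ground_truth$chain,
              file.path(dir, "ground_truth_chain.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$ground_truth$subjects,
              file.path(dir, "ground_truth_subjects.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
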