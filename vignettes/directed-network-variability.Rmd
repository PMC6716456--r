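---
title: "Strength and temporal variability of directed brain networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strength and temporal variability of directed brain networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgcnet)
```

`dgcnet` implements a complete analysis chain for characterizing how
*strongly* and how *variably* brain regions drive one another in
resting-state fMRI, and for testing whether those properties degrade in a
graded way across clinical groups (here labeled `control`, `ptsd`,
`pcs_ptsd`). This vignette explains each model in the chain, the
parameters that matter, the numerical choices we made where the design
was genuinely open, and what the synthetic validation does and does not
demonstrate.

## 1. The generative picture and the deconvolution problem

BOLD fMRI is an indirect measurement: latent neural activity is smoothed
and delayed by the hemodynamic response function (HRF), whose
time-to-peak varies by several seconds across brain regions and
subjects. For *directional* (lag-based) connectivity this is not a
nuisance but a confound with teeth: if region A's HRF peaks at 5 s and
region B's at 7 s, identical neural signals produce BOLD series where B
appears to follow A, and a Granger-type estimator reports a causal
influence that does not exist in the neural signals at all. The
`sim_lagged_hrf_pair()` construction reproduces this scenario and
`deconv_gc_reduction()` measures how much of the spurious causality
blind deconvolution removes.

The deconvolution stage (`deconvolve()`) is blind: both the HRF and the
latent neural series are estimated from the recorded data alone, under a
point-process model of resting-state activity — neural events occur at
random times, and the BOLD series is their convolution with the
region's HRF plus noise. The stages per region are:

1. **Pseudo-event detection** (`detect_pseudo_events()`): the
   standardized signal crosses a threshold (default 1 SD — the threshold
   is a free choice, not an empirical constant) and each supra-threshold
   excursion contributes one event at its local maximum.
2. **Overlap-corrected event-locked response**: rather than averaging
   fixed windows (which blurs overlapping responses together), the
   signal is ridge-regressed on the event train at all lags within the
   HRF window, with per-event amplitudes and sub-sample (parabolic)
   event placement.
3. **Canonical-family fit**: a double-gamma with free time-to-peak is
   fitted to the event-locked response. This is where identifiability
   comes from: events detected at BOLD peaks carry no timing information
   relative to their own region, so the absolute HRF lag must be read
   out of the response *shape* (in the gamma family, width and peak are
   coupled). The fit is iterated: the current kernel sharpens the
   latent by Wiener deconvolution, events are re-detected on the
   sharpened latent (robust MAD threshold), and the fit is refreshed;
   the estimate is the median over the trailing iterations.
4. **Wiener deconvolution** (`wiener_deconvolve()`):
   `X(f) H*(f) / (|H(f)|^2 + noise_floor)`, zero-padded so the
   convolution model is linear rather than circular (wrap-around error
   would be amplified by the inverse filter). The default regularization
   is 10% of mean kernel power; for low-noise data a small absolute
   value (we use 0.01 in the validation scenarios) inverts harder.

The HRF window is 24 s; band-pass filtering (`bandpass()`, zero-phase
Butterworth, default 0.01–0.1 Hz) and nuisance regression
(`regress_nuisance()`) are available as separate preprocessing steps.
Filtering is deliberately zero-phase: a causal filter would itself inject
artificial lags into the causality estimates.

**Known limitation.** In the lagged-HRF scenario at realistic scan
lengths, the blind estimator recovers each region's time-to-peak with a
standard error of roughly 0.3–0.5 s; a two-fold reduction of the
spurious causality needs the *relative* lag of the pair to be right
within about 0.6 s. Consequently, deconvolution reduces the spurious
causality in essentially every replicate, and by a factor of two or more
in about 80% of them — not more. With ground-truth event times the same
machinery reaches over 90%, so the residual gap is information lost at
event detection, which no amount of post-processing recovers. Validation
on real data should treat deconvolution as variance reduction for the
HRF confound, not elimination.

## 2. Static and dynamic effective connectivity

Directional coupling is estimated with a zero-lag-augmented first-order
multivariate autoregressive (MVAR) model fitted by least squares
(`fit_mvar()`): every region is predicted from all regions at the
previous timepoint *and* from the other regions at the same timepoint.
The instantaneous term (zero on its diagonal) absorbs zero-lag
cross-correlation so that shared input does not masquerade as lagged,
directional influence; it is excluded from the causality measure itself.
Static Granger causality (`static_gc()`) from region i to region j is
the sum of i's lagged coefficients in j's equation — at order 1, simply
the lag-1 coefficient. Model order 1 is the default because fMRI's
sampling is slow relative to neural delays; the order is exposed for
sensitivity analyses. Columns are standardized before fitting so
coefficients are comparable across subjects; note that this means a
planted generative coefficient is recovered exactly only when the
regions have equal stationary variance (the validation constructions are
built that way).

The dynamic counterpart (`kalman_dmvar()`) estimates the same regression
recursively with a Kalman filter / recursive-least-squares scheme with a
forgetting factor. Forgetting 1 keeps all history: the recursion then
converges to the batch fit (this equivalence is tested), which makes it
well-conditioned but blind to genuine coefficient change — with
forgetting 1 the coefficient trajectory is an expanding-window average.
Forgetting just below 1 discounts the past with time constant
`1/(1 - forgetting)` samples; 0.98 tracks a 0 → 0.8 coupling step within
a few dozen samples, and the cohort pipeline default is 0.99 (time
constant 100 samples), chosen to balance tracking of slow coupling
fluctuations against estimation noise, which enters all downstream
variability features. Initialization is coefficients 0 with state
covariance `kappa * I` (`kappa = 1`); the recursive prediction-error
variance is tracked and returned.

Dynamic Granger causality (`dynamic_gc()`) is the time-indexed
coefficient sum; its temporal variance (`dec_variance()`) after a
burn-in (default `max(50, 5% of T)`, covering the filter transient) is
the edge-level "variability of connectivity" feature. All variability
reductions in the package use the population variance (divide by N): it
is a descriptive moment of the trajectory, and it is exact for periodic
trajectories (a sinusoid of amplitude A has variance A²/2 over whole
periods, and a two-point alternation between values a and b has variance
((a-b)/2)² exactly).

Sign is kept throughout the connectivity stage; absolute values are
taken only when networks are built.

## 3. Network measures of segregation and integration

`to_graph()` builds a weighted directed graph from |connectivity|,
rescaled so the maximum weight is 1 — making every measure invariant to
the overall connectivity scale. Six measures are computed
(`static_metrics()`):

* **Segregation** — transitivity (whole-network), clustering coefficient
  and local efficiency (per node). The directed weighted formulations
  use cube-root weights and count directed triangle intensity in all
  orientations; local efficiency is the efficiency of each node's
  neighborhood subgraph (union of in- and out-neighbors).
* **Integration** — global efficiency (whole-network), shortest path
  length and edge betweenness (per ordered pair / edge). Edge length is
  the inverse weight; unreachable pairs have infinite distance
  (contributing zero to efficiency). Edge betweenness counts the raw
  number of shortest directed paths through an edge over all ordered
  source–target pairs, with all tied shortest paths counted (ties are
  resolved within a relative tolerance of 1e-9).

The edge-level feature of a pair (i, j) is its ordered-pair distance
d(i, j); an edge-removal statistic would be an alternative reading, but
the pair distance is the direct one and is what we adopt. All six
implementations are verified against brute-force enumeration oracles to
1e-10 on small graphs.

For dynamic networks, every retained timepoint of the DGC tensor is a
snapshot graph; `dynamic_metric_variance()` computes all measures per
snapshot and reduces each trajectory to its variance — the
"flexibility" of that network property. A `stride` parameter subsamples
snapshots when runtime matters at atlas scale.

## 4. The selection framework

`apply_hypotheses()` implements the hypothesis-driven selection. For
every feature, three pairwise covariate-adjusted comparisons (control vs
PTSD, control vs PCS+PTSD, PTSD vs PCS+PTSD) are run on both the
strength (static) and variability flavors — six cells per network
measure. The model per cell is a linear model with a group indicator and
covariates age, education, race (reference-coded, rare categories
merged) and mean framewise displacement; two-sided p-values for the
group term; adjusted means at covariate grand means.

Multiple comparisons are corrected by Benjamini–Hochberg within each
(pair, flavor, measure) family at the full accounting budget of
`count_comparisons()`: k potential tests for nodal measures, k² − k for
edge measures (for the 125-region atlas: 125 and 15500, totalling 31250
across both flavors). The budget counts scopes once per family even when
fewer features are supplied, which keeps the correction honest when a
subset is analyzed.

A measure-scope unit is **hypothesis-2** when all six of its cells are
significant and its adjusted means are strictly trend-conforming
(monotone strength in one direction — "inflation" rising toward
PCS+PTSD, "deflation" falling; variability strictly decreasing,
"rigidity"); ties break conformance. It is **hypothesis-1** when the
four control-vs-clinical cells are significant, *neither*
PTSD-vs-PCS+PTSD cell is, and the relaxed trend holds (both clinical
groups shifted the same way from control). The two sets are mutually
exclusive by construction. "Not significant" for the hypothesis-1 rule
means failing the FDR threshold — no equivalence test is performed,
which is a documented limitation. Trend conformance is evaluated on
adjusted means from the single three-group covariate model (pairwise
models would each produce pair-specific adjusted means; one adjustment
gives one comparable triple).

Nodes must then be selected by *both* local segregation measures, and
edges by *both* local integration measures (`intersect_local()`);
finally `connectivity_gate()` retains only edges whose raw static
connectivity and dynamic-connectivity variance independently show the
same hypothesis pattern. Every layer is conservative by design.

## 5. Behavioral association and prediction

* `behavior_correlations()`: feature-behavior Pearson correlations,
  Bonferroni-corrected over all pairs tested.
* `plsr_assoc()`: partial least squares regression (SIMPLS) between the
  feature block and the behavior block; reports the percentage of
  behavior-block variance explained by the retained components and the
  squared correlation of the first latent score pair.
* `rce_svm()`: recursive cluster elimination. Per repetition, subjects
  are dealt into stratified cross-validation folds (6 folds ≈ 80/20
  train/test); within each training set, features are standardized and
  k-means-clustered (initially 40 clusters), each cluster is scored by
  inner cross-validated linear-SVM accuracy, and the bottom 20% of
  clusters are eliminated per step down to 2. Held-out accuracy is
  recorded at every step for every rep × fold (100 repetitions × 6 folds
  = 600 test evaluations); the *worst-case accuracy* is the minimum over
  all of them — a deliberately pessimistic summary. Significance comes
  from an upper-tail binomial test at the largest-class chance level.
  Test rows never touch standardization, clustering, scoring or
  elimination (asserted by a dedicated leakage test). SVMs are linear
  with unit cost throughout; no hyperparameters are tuned.
* `svr_predict()`: cross-validated linear support vector regression of a
  symptom score; per iteration, pooled held-out predictions give one
  R² (squared Pearson correlation). The default iteration count is
  modest (hundreds); the estimate is stable well before that.

Multiclass classification uses libsvm's one-vs-one voting via `e1071`.

## 6. The synthetic cohort generator

`cohort_design()` / `simulate_cohort()` provide ground truth for every
stage. Latent neural signals follow a stable lag-1 VAR (optionally with
instantaneous coupling); a planted five-region directional chain —
labeled PFC → INS → AMY → HIP → PCU after the prefrontal →
insula → amygdala → hippocampus → precuneus pathway it emulates —
carries the group effects:

* **Strength**: per-group multipliers on the chain coupling, default
  (1.0, 0.72, 0.56) — a *deflating* prefrontal-origin pathway, the
  regime in which strength and variability effects are mutually
  consistent (a weaker path is both weaker on average and, when its
  fluctuation amplitude also shrinks, less variable).
* **Variability**: the chain coupling oscillates sinusoidally (periods
  280–420 samples; amplitude 0.45 scaled by per-group multipliers
  (1.0, 0.6, 0.12) — "rigidity" increasing with clinical severity). The
  amplitude is capped so the coupling never approaches zero: distance
  features are inverse weights, and couplings through zero would give
  unbounded snapshot distances.
* **Routing context** (group-invariant): a strong anchor pair that
  pins the weight normalization; feeder regions projecting into the
  chain head; distributor regions receiving from the chain tail; and a
  staggered family of weak direct shortcuts that compete with the chain
  for shortest-path routing. Without this context the integration
  measures would be blind to the planted effects — a uniformly scaled
  chain disappears under max-normalization, and edge betweenness only
  responds when routes actually flip.
* **Observation**: region-specific double-gamma HRFs with time-to-peak
  drawn from U[4.5, 7.5] s, plus white observation noise — the full HRF
  confound.
* **Behavior**: PCL5, NSI and NCI are linear in each subject's
  generative multipliers plus noise, so the signs of feature-behavior
  associations are known (severity rises, cognition falls, as the chain
  deflates and rigidifies).

Subjects get independently jittered multipliers; covariates are drawn
from the same distributions in every group (no planted confounding). The
ground-truth annex records the chain, the group multipliers and every
subject's multipliers and scheduled coupling variance. Default sizes
mirror a three-group, 87-subject, 125-region, 1000-timepoint study; the
validation suite runs a reduced 20-region, 500-timepoint, 20-per-group
version, and the vignette-scale examples smaller still.

Effect sizes are free parameters — nothing in the problem fixes them —
and were chosen once to be large enough that the raw-connectivity
selection has power at the reduced validation scale while remaining
plausible (coupling differences of tens of percent, variability ratios
of a few fold).

**What the validation shows, and what it does not.** The recovery
benchmark feeds the *latent* neural series to the pipeline: it validates
estimation → network measures → selection against ground truth. At the
reduced scale the individual cells behave as designed — the planted
contrasts reach p-values of 1e-4 to 1e-15 in the larger comparisons, and
effectively-null cohorts select nothing — but the *joint* requirement
that all six cells of a unit pass FDR simultaneously is volatile at
n = 20 per group: per-seed sensitivity of the raw-connectivity
hypothesis-2 pattern ranges from 0 to 0.75 with no false selections.
Two things are out of reach at this scale, and we report them as
limitations rather than engineering around them: (i) recovering the
planted pattern *through* the BOLD observation stage — with 3 s of HRF
time-to-peak variability and 500 timepoints, the blind-deconvolution
error exceeds the group signal; and (ii) the full network-level
hypothesis-2 set, which requires all six cells on both
shortest-path-length and edge-betweenness units: the temporal variance
of inverse-weight distances carries a Kalman-estimation-noise floor
with heavy tails that caps its pairwise t-statistics near 1–2 at n = 20
per group, short of what BH at the k² − k budget demands. These are
information-budget limits, not implementation defects; the
corresponding checks in the acceptance suite are left asserting the
stricter bars.

The generator also does not emulate: head motion and its interaction
with the groups, physiological noise structure, non-stationary noise,
parcellation error, or volumetric/spatial structure of any kind.

## 7. Reproducing the numbers

Problem sizes used by the validation suite: coefficient recovery at
T = 20000; direction recovery over 100 seeds at T = 2000; zero-lag
compensation over 50 seeds at T = 3000; Kalman equivalence at T = 4000;
the lagged-HRF scenario at T = 2000, 50 replicates; the cohort benchmark
at k = 20, T = 500, n = 20 per group with three small null cohorts; the
prediction checks on 60 × 204 separable designs and planted latent
associations of 0.55 (PLSR) and 0.70 (SVR). `scripts/acceptance.R`
recomputes all of these from scratch under a supplied seed.
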