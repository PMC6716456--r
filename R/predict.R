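#' Feature-behavior correlation table with Bonferroni correction
#'
#' Pearson correlation of every feature against every behavioral score,
#' with two-sided p-values Bonferroni-adjusted over all pairs tested.
#'
#' @param features data.frame or matrix (subjects x features).
#' @param behaviors data.frame or matrix (subjects x scores).
#' @return data.frame: `feature`, `behavior`, `r`, `p`, `p_bonferroni`,
#'   `significant` (adjusted p < 0.05); attribute `n_tests`.
#' @export
behavior_correlations <- function(features, behaviors) {
  F <- as.matrix(features); B <- as.matrix(behaviors)
  stopifnot(nrow(F) == nrow(B))
  if (nrow(F) < 10L) stop("need at least 10 complete subject rows")
  n_tests <- ncol(F) * ncol(B)
  out <- expand.grid(feature = colnames(F), behavior = colnames(B),
                     stringsAsFactors = FALSE)
  rp <- t(mapply(function(f, b) {
    ct <- cor.test(F[, f], B[, b])
    c(ct$estimate, ct$p.value)
  }, out$feature, out$behavior))
  out$r <- rp[, 1]
  out$p <- rp[, 2]
  out$p_bonferroni <- pmin(1, out$p * n_tests)
  out$significant <- out$p_bonferroni < 0.05
  attr(out, "n_tests") <- n_tests
  out
}

# SIMPLS partial least squares on centered/scaled blocks; returns weights,
# scores and loadings for n_comp components
simpls <- function(X, Y, n_comp) {
  S <- crossprod(X, Y)
  p <- ncol(X)
  Rw <- matrix(0, p, n_comp); Tt <- matrix(0, nrow(X), n_comp)
  Pl <- matrix(0, p, n_comp); Ql <- matrix(0, ncol(Y), n_comp)
  V <- matrix(0, p, n_comp)
  for (a in seq_len(n_comp)) {
    r <- svd(S, nu = 1, nv = 0)$u
    t <- X %*% r
    t <- t - mean(t)
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12) { n_comp <- a - 1L; break }
    t <- t / nt; r <- r / nt
    pl <- crossprod(X, t)
    ql <- crossprod(Y, t)
    v <- pl
    if (a > 1) v <- v - V[, 1:(a - 1), drop = FALSE] %*%
        crossprod(V[, 1:(a - 1), drop = FALSE], pl)
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    Rw[, a] <- r; Tt[, a] <- t; Pl[, a] <- pl; Ql[, a] <- ql; V[, a] <- v
  }
  idx <- seq_len(n_comp)
  list(weights = Rw[, idx, drop = FALSE], scores = Tt[, idx, drop = FALSE],
       x_loadings = Pl[, idx, drop = FALSE],
       y_loadings = Ql[, idx, drop = FALSE], n_comp = n_comp)
}

#' Latent-space association between features and behaviors via PLSR
#'
#' Partial least squares regression (SIMPLS) maps the feature block and
#' the behavior block into a shared latent space. Reports the percentage
#' of behavior-block variance explained by the retained components and
#' the squared correlation (with p-value) of the first latent score pair.
#'
#' @param X_features subjects x features matrix (standardized
#'   internally).
#' @param Y_behaviors subjects x behaviors matrix (standardized
#'   internally).
#' @param n_components number of latent components.
#' @return `plsr_result` list: `n_components`,
#'   `pct_variance_explained` (of the behavior block, 0-100),
#'   `latent_r2`, `latent_p`, `x_scores`, `y_scores`.
#' @export
plsr_assoc <- function(X_features, Y_behaviors, n_components = 2L) {
  X <- scale(as.matrix(X_features)); Y <- scale(as.matrix(Y_behaviors))
  X[, !is.finite(colSums(X))] <- 0
  fit <- simpls(X, Y, n_components)
  Yhat <- fit$scores %*% t(fit$y_loadings)  # scores are orthonormal
  pct <- 100 * (1 - sum((Y - Yhat)^2) / sum(Y^2))
  u1 <- Y %*% fit$y_loadings[, 1]
  t1 <- fit$scores[, 1]
  ct <- cor.test(t1, u1)
  structure(list(n_components = fit$n_comp,
                 pct_variance_explained = pct,
                 latent_r2 = unname(ct$estimate^2), latent_p = ct$p.value,
                 x_scores = fit$scores, y_scores = Y %*% fit$y_loadings),
            class = "plsr_result")
}

#' Upper-tail binomial significance of a classification accuracy
#'
#' Probability of observing at least `n_correct` successes in `n_total`
#' trials under a binomial null with success probability `chance`.
#'
#' @param n_correct,n_total observed correct classifications and trials.
#' @param chance null success probability (e.g. the largest class
#'   proportion).
#' @return p-value.
#' @export
binomial_significance <- function(n_correct, n_total, chance) {
  stopifnot(n_correct <= n_total, chance > 0, chance < 1)
  pbinom(n_correct - 1, n_total, chance, lower.tail = FALSE)
}

# stratified fold assignment: per class, shuffled indices dealt cyclically
stratified_folds <- function(labels, folds) {
  out <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    out[idx] <- rep_len(seq_len(folds), length(idx))
  }
  out
}

svm_accuracy <- function(Xtr, ytr, Xte, yte) {
  if (nlevels(droplevels(ytr)) < 2L) return(mean(yte == ytr[1]))
  fit <- e1071::svm(Xtr, droplevels(ytr), kernel = "linear", cost = 1,
                    scale = FALSE)
  mean(predict(fit, Xte) == yte)
}

# inner cross-validated accuracy of one feature subset on the training data
inner_cv_accuracy <- function(X, y, cols, inner_folds) {
  fa <- stratified_folds(y, inner_folds)
  acc <- vapply(seq_len(inner_folds), function(f) {
    tr <- fa != f
    svm_accuracy(X[tr, cols, drop = FALSE], y[tr],
                 X[!tr, cols, drop = FALSE], y[!tr])
  }, 0)
  mean(acc)
}

#' Recursive cluster elimination SVM classification
#'
#' For each of `reps` repetitions, subjects are dealt into `folds`
#' stratified cross-validation folds; each fold in turn is the test set
#' (so training uses (folds-1)/folds of the participants, about 80% with
#' 6 folds) and every rep x fold contributes one test evaluation, `reps *
#' folds` in total. Within each training set, features are standardized
#' (training statistics only), k-means-clustered into the current number
#' of clusters, and each cluster is scored by the inner cross-validated
#' accuracy of a linear SVM using only that cluster's features. At every
#' RCE step the held-out test accuracy of the currently surviving
#' features is recorded, then the bottom `elim_frac` of clusters is
#' eliminated; steps continue until `clusters_final` clusters remain.
#' The worst-case accuracy is the minimum test accuracy over all rep x
#' fold evaluations at the final step. Test rows never influence
#' standardization, clustering, scoring, or elimination.
#'
#' @param features subjects x features matrix or data.frame.
#' @param labels class factor (2 or 3 groups).
#' @param reps number of repetitions.
#' @param folds outer cross-validation folds.
#' @param clusters_init initial number of feature clusters.
#' @param elim_frac fraction of clusters eliminated per step.
#' @param clusters_final clusters remaining at the final step.
#' @param inner_folds folds of the cluster-scoring inner CV.
#' @param chance null accuracy for the binomial test (default: largest
#'   class proportion).
#' @param seed integer seed.
#' @return `rce_result` list: `steps` (per-step cluster count, mean and
#'   minimum test accuracy, pooled binomial p), `worst_case_accuracy`,
#'   `mean_accuracy` (final step), `n_evaluations`, `feature_freq`
#'   (survival frequency of each feature at the final step),
#'   `top_features`, `chance`, `fold_table` (rep/fold test indices).
#' @export
rce_svm <- function(features, labels, reps = 10L, folds = 6L,
                    clusters_init = 40L, elim_frac = 0.2,
                    clusters_final = 2L, inner_folds = 3L, chance = NULL,
                    seed = 1L) {
  X <- as.matrix(features)
  y <- droplevels(factor(labels))
  stopifnot(nlevels(y) >= 2L, nrow(X) == length(y))
  if (min(table(y)) < folds)
    stop("every class needs at least `folds` members")
  if (is.null(chance)) chance <- max(table(y)) / length(y)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(p))

  # cluster-count schedule
  sched <- integer(0)
  ncl <- min(clusters_init, p)
  repeat {
    sched <- c(sched, ncl)
    if (ncl <= clusters_final) break
    ncl <- max(clusters_final, ncl - max(1L, ceiling(elim_frac * ncl)))
  }
  n_steps <- length(sched)
  acc <- matrix(NA_real_, reps * folds, n_steps)
  correct <- matrix(0, reps * folds, n_steps)
  ntest <- integer(reps * folds)
  surv_final <- numeric(p); names(surv_final) <- colnames(X)
  fold_table <- vector("list", reps * folds)

  ev <- 0L
  for (r in seq_len(reps)) {
    set.seed(seed + r)
    fa <- stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      ev <- ev + 1L
      te <- fa == f
      fold_table[[ev]] <- list(rep = r, fold = f, test = which(te))
      Xtr <- X[!te, , drop = FALSE]; ytr <- y[!te]
      mu <- colMeans(Xtr); sg <- apply(Xtr, 2, sd); sg[sg == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
      Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sg, "/")
      yte <- y[te]
      active <- seq_len(p)
      for (s in seq_len(n_steps)) {
        ncl <- min(sched[s], length(active))
        # test evaluation with the currently surviving features
        a <- svm_accuracy(Xtr[, active, drop = FALSE], ytr,
                          Xte[, active, drop = FALSE], yte)
        acc[ev, s] <- a
        correct[ev, s] <- round(a * sum(te))
        if (s == n_steps) break
        cl <- feature_clusters(Xtr[, active, drop = FALSE], ncl)
        scores <- vapply(seq_len(ncl), function(ci)
          inner_cv_accuracy(Xtr, ytr, active[cl == ci], inner_folds), 0)
        keep_n <- min(sched[s + 1L], ncl)
        # ties broken by cluster index: order() is stable
        kept <- order(-scores)[seq_len(keep_n)]
        active <- active[cl %in% kept]
      }
      surv_final[active] <- surv_final[active] + 1
      fold_table[[ev]]$surviving <- colnames(X)[active]
      ntest[ev] <- sum(te)
    }
  }
  freq <- surv_final / (reps * folds)
  steps <- data.frame(
    step = seq_len(n_steps), n_clusters = sched,
    mean_accuracy = colMeans(acc), min_accuracy = apply(acc, 2, min),
    binom_p = vapply(seq_len(n_steps), function(s)
      binomial_significance(sum(correct[, s]), sum(ntest) , chance), 0))
  structure(list(steps = steps,
                 worst_case_accuracy = steps$min_accuracy[n_steps],
                 mean_accuracy = steps$mean_accuracy[n_steps],
                 n_evaluations = as.integer(reps * folds),
                 feature_freq = freq,
                 top_features = names(freq)[freq > 0.5],
                 chance = chance, fold_table = fold_table,
                 accuracy = acc),
            class = "rce_result")
}

# k-means clustering of features (columns) on the training rows; falls
# back to size-balanced assignment when centers collide
feature_clusters <- function(Xtr, ncl) {
  M <- t(Xtr)
  if (ncl >= nrow(M)) return(seq_len(nrow(M)))
  km <- tryCatch(kmeans(M, centers = ncl, nstart = 2, iter.max = 30),
                 error = function(e) NULL)
  if (is.null(km)) return(rep_len(seq_len(ncl), nrow(M)))
  km$cluster
}

#' Cross-validated linear support vector regression of a symptom score
#'
#' Per iteration: subjects are randomly dealt into `folds` folds; a
#' linear SVR is trained on all but one fold and predicts the held-out
#' fold; pooled predictions give one R-squared (squared Pearson
#' correlation of predicted vs true) per iteration.
#'
#' @param features subjects x features.
#' @param score numeric target (e.g. PCL5).
#' @param folds cross-validation folds.
#' @param iterations number of random-fold iterations.
#' @param seed integer seed.
#' @return `svr_result` list: `r2` (per iteration), `mean_r2`, `sd_r2`.
#' @export
svr_predict <- function(features, score, folds = 6L, iterations = 100L,
                        seed = 1L) {
  X <- as.matrix(features)
  stopifnot(nrow(X) == length(score))
  set.seed(seed)
  r2 <- vapply(seq_len(iterations), function(it) {
    fa <- rep_len(seq_len(folds), nrow(X))[sample(nrow(X))]
    pred <- numeric(nrow(X))
    for (f in seq_len(folds)) {
      te <- fa == f
      fit <- e1071::svm(X[!te, , drop = FALSE], score[!te],
                        kernel = "linear", cost = 1,
                        type = "eps-regression")
      pred[te] <- predict(fit, X[te, , drop = FALSE])
    }
    cor(pred, score)^2
  }, 0)
  structure(list(r2 = r2, mean_r2 = mean(r2), sd_r2 = sd(r2),
                 folds = folds, iterations = iterations),
            class = "svr_result")
}
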