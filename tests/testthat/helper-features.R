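# Build a synthetic feature table with planted group patterns, bypassing
# the simulation stages, to exercise the selection framework directly.
# `effects` maps feature names to length-3 group mean vectors
# (control, ptsd, pcs_ptsd); all other features are pure noise.
make_feature_table <- function(n_per_group = c(15, 15, 15), labels = c("A", "B", "C"),
                               effects = list(), noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  k <- length(labels)
  n <- sum(n_per_group)
  group <- factor(rep(c("control", "ptsd", "pcs_ptsd"), n_per_group),
                  levels = c("control", "ptsd", "pcs_ptsd"))
  edges <- expand.grid(a = labels, b = labels, stringsAsFactors = FALSE)
  edges <- edges[edges$a != edges$b, ]
  enm <- paste0("edge:", edges$a, ">", edges$b)
  cols <- c(
    "transitivity.static.global", "effglob.static.global",
    "transitivity.var.global", "effglob.var.global",
    paste0("cc.static.node:", labels), paste0("cc.var.node:", labels),
    paste0("effloc.static.node:", labels), paste0("effloc.var.node:", labels),
    paste0("spl.static.", enm), paste0("spl.var.", enm),
    paste0("eb.static.", enm), paste0("eb.var.", enm),
    paste0("sec.static.", enm), paste0("vdec.var.", enm))
  F <- matrix(rnorm(n * length(cols), sd = noise_sd), n, length(cols),
              dimnames = list(NULL, cols))
  gi <- as.integer(group)
  for (nm in names(effects))
    F[, nm] <- F[, nm] + effects[[nm]][gi]
  manifest <- data.frame(
    subject = sprintf("S%02d", seq_len(n)), group = group,
    age = round(rnorm(n, 33, 6)), education = round(rnorm(n, 14, 2)),
    race = sample(c("white", "black", "other"), n, TRUE, c(0.6, 0.25, 0.15)),
    motion = abs(rnorm(n, 0.1, 0.03)), stringsAsFactors = FALSE)
  list(features = as.data.frame(F, check.names = FALSE), manifest = manifest)
}

# standard planted patterns: deflation+rigidity gradients
h2_pattern <- c(3, 2, 1)
h1_pattern <- c(3, 1, 1)

# apply a pattern to every cell of a measure-scope unit (both flavors)
unit_effects <- function(scope, pattern, measures = c("spl", "eb"),
                         conn = TRUE) {
  out <- list()
  for (m in measures) {
    out[[paste0(m, ".static.", scope)]] <- pattern
    out[[paste0(m, ".var.", scope)]] <- pattern
  }
  if (conn) {
    out[[paste0("sec.static.", scope)]] <- pattern
    out[[paste0("vdec.var.", scope)]] <- pattern
  }
  out
}
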