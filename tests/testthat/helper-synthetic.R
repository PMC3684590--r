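# Shared fixtures and independent oracles, all built in code at test time.

# Small cohort + planted edge features for selection/classification tests.
make_fixture <- function(n_pat = 12, n_ctl = 12, n_rois = 20, n_planted = 4,
                         shift = 0.5, qol_r = 0.65, seed = 1) {
  coh <- simulate_cohort(n_pat, n_ctl, seed = seed)
  eff <- default_effects(n_rois = n_rois, n_planted = n_planted,
                         group_shift = shift, qol_r = qol_r,
                         seed = seed + 1000)
  X <- simulate_edge_data(coh, n_rois = n_rois, effects = eff,
                          seed = seed + 2000)
  list(cohort = coh, effects = eff, features = X)
}

# AUC by exhaustive concordant-pair counting (ties count 1/2).
auc_paircount <- function(dv, labels) {
  pat <- dv[labels == "patient"]
  ctl <- dv[labels == "control"]
  mean(outer(pat, ctl, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Textbook pooled-variance two-sample t statistic.
textbook_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Partial correlation by explicit double residualization (the defining
# construction, used as the independent oracle for the matrix-inverse route).
partial_cor_resid <- function(x, y, z) {
  rx <- residuals(lm(x ~ as.matrix(z)))
  ry <- residuals(lm(y ~ as.matrix(z)))
  cor(rx, ry)
}
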