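test_that("relative_error does the arithmetic and flags zero actuals", {
  expect_equal(relative_error(55, 50), 0.1)
  expect_equal(relative_error(c(3, 7), c(3, 7)), c(0, 0))
  set.seed(60)
  pred <- rnorm(20, 50, 5); act <- rnorm(20, 50, 5)
  # scalar-loop oracle
  oracle <- vapply(1:20, function(i) abs(pred[i] - act[i]) / abs(act[i]),
                   numeric(1))
  expect_equal(relative_error(pred, act), oracle)
  out <- relative_error(c(1, 2), c(0, 4))
  expect_true(is.na(out[1]))
  expect_equal(out[2], 0.5)
  expect_error(relative_error(1:3, 1:2), "length")
})

test_that("CSI normalizes predicted QoL to unit mean", {
  expect_equal(compute_csi(c(80, 80, 80)), c(1, 1, 1))
  expect_equal(compute_csi(c(60, 100)), c(0.75, 1.25))
  set.seed(61)
  for (i in 1:10) {
    x <- rnorm(sample(5:30, 1), 75, 12)
    expect_lt(abs(mean(compute_csi(x)) - 1), 1e-12)
  }
  expect_error(compute_csi(80), "at least 2")
  expect_error(compute_csi(c(-1, 1)), "zero")
})

test_that("partial correlation matches the residualization oracle", {
  set.seed(62)
  n <- 30
  for (i in 1:10) {
    x <- rnorm(n); z <- matrix(rnorm(n * 2), n)
    y <- 0.5 * x + 0.3 * z[, 1] + rnorm(n)
    pc <- partial_cor(x, y, z)
    expect_equal(pc$r, partial_cor_resid(x, y, z), tolerance = 1e-10)
    expect_equal(pc$df, n - 4)
  }
  # a covariate orthogonal to both variables leaves r unchanged
  x <- rnorm(n); y <- 0.6 * x + rnorm(n)
  z <- qr.resid(qr(cbind(1, x, y)), rnorm(n))
  pc <- partial_cor(x, y, z)
  expect_equal(pc$r, cor(x, y), tolerance = 1e-10)
  # exact anti-correlation
  pc2 <- partial_cor(1:10, -(1:10))
  expect_equal(pc2$r, -1)
  expect_lt(pc2$p, 1e-12)
  expect_error(partial_cor(rep(1, 5), rnorm(5)), "constant")
  expect_error(partial_cor(rnorm(5), rnorm(5), rep(2, 5)), "constant")
})

test_that("LOO-SVR predicts realizable targets and not pure noise", {
  set.seed(63)
  n <- 20
  X <- matrix(rnorm(n * 50, 0.3, 0.25), n)
  target <- 50 + 30 * X[, 7]  # exactly linear in one stable edge
  pred <- predict_scores(X, target, stable = 7L)
  expect_lt(mean(relative_error(pred, target)), 0.05)
  # an unrelated target is predicted no better than the training mean
  ratio <- vapply(1:10, function(s) {
    set.seed(6300 + s)
    Xs <- matrix(rnorm(n * 30, 0.3, 0.25), n)
    y <- rnorm(n, 40, 10)
    pred <- predict_scores(Xs, y, stable = 1:5)
    base <- vapply(seq_len(n), function(k) mean(y[-k]), numeric(1))
    mean(relative_error(pred, y)) / mean(relative_error(base, y))
  }, numeric(1))
  expect_gt(mean(ratio), 0.8)
  expect_error(predict_scores(X, rep(3, n), 7L), "constant")
  expect_error(predict_scores(X[1:4, ], target[1:4], 7L), "at least 5")
})

test_that("csi_table runs the severity stage for patients only", {
  fx <- make_fixture(n_pat = 12, n_ctl = 12, n_rois = 15, n_planted = 4,
                     shift = 0.5, qol_r = 0.7, seed = 64)
  tab <- csi_table(fx$cohort, fx$features, fx$effects$feature_indices)
  expect_s3_class(tab, "csi_table")
  expect_equal(nrow(tab), 12)
  expect_true(all(grepl("^FD", tab$subject_id)))
  expect_lt(abs(mean(tab$csi) - 1), 1e-12)
  # duration, simulated independent of connectivity, predicts worst
  errs <- vapply(c("ndi_symptom", "sds", "sas", "duration_months"),
                 function(v) {
    pat <- fx$cohort$group == "patient"
    pred <- predict_scores(fx$features[pat, ], fx$cohort[[v]][pat],
                           fx$effects$feature_indices)
    mean(relative_error(pred, fx$cohort[[v]][pat]), na.rm = TRUE)
  }, numeric(1))
  expect_equal(names(which.max(errs)), "duration_months")
})

test_that("csi_correlations reports plain and partial associations", {
  fx <- make_fixture(n_pat = 15, n_ctl = 12, n_rois = 15, n_planted = 4,
                     shift = 0.5, qol_r = 0.7, seed = 65)
  tab <- csi_table(fx$cohort, fx$features, fx$effects$feature_indices)
  cc <- csi_correlations(tab)
  expect_equal(cc$variable,
               c("ndi_symptom", "sds", "sas", "duration_months"))
  expect_equal(cc$covariates[cc$variable == "ndi_symptom"], "sds+sas")
  expect_equal(cc$covariates[cc$variable == "sds"], "ndi_symptom+sas")
  expect_true(all(cc$p >= 0 & cc$p <= 1))
  # partials agree with the residualization oracle
  pr <- partial_cor_resid(tab$csi, tab$sds,
                          as.matrix(tab[, c("ndi_symptom", "sas")]))
  expect_equal(cc$partial_r[cc$variable == "sds"], pr, tolerance = 1e-10)
})

test_that("edge-QoL partial correlation recovers planted slope signs", {
  # constant age: partial equals plain correlation
  set.seed(66)
  X <- matrix(rnorm(30 * 20), 30)
  qol <- rnorm(30, 75, 10)
  pc <- edge_qol_partial_corr(X, qol, age = rep(23, 30), indices = 1:20)
  expect_equal(pc$r, as.vector(cor(qol, X)), tolerance = 1e-10)
  # planted negative slopes: negative sign recovered in >= 90% of edges/seeds
  signs <- unlist(lapply(1:10, function(s) {
    coh <- simulate_cohort(40, 2, seed = 6600 + s)
    eff <- planted_effects(1:5, group_shift = 0, qol_slope = -0.02,
                           noise_sd = 0.25)
    Xs <- simulate_edge_data(coh, 15, eff, seed = 6700 + s)
    pat <- coh$group == "patient"
    edge_qol_partial_corr(Xs[pat, ], coh$ndi_qol[pat], coh$age_years[pat],
                          1:5)$r < 0
  }))
  expect_gte(mean(signs), 0.9)
  # 65% negative planted slopes: recovered fraction within 10 points
  fracs <- vapply(1:10, function(s) {
    coh <- simulate_cohort(40, 2, seed = 6800 + s)
    eff <- default_effects(n_rois = 15, n_planted = 20, group_shift = 0,
                           qol_r = 0.65, frac_negative = 0.65,
                           seed = 6900 + s)
    Xs <- simulate_edge_data(coh, 15, eff, seed = 7000 + s)
    pat <- coh$group == "patient"
    r <- edge_qol_partial_corr(Xs[pat, ], coh$ndi_qol[pat],
                               coh$age_years[pat],
                               eff$feature_indices)$r
    mean(r < 0)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.65), 0.10)
})
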