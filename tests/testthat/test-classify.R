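test_that("classification reports do the confusion arithmetic", {
  r <- classification_report(35, 40, 32, 40)
  expect_equal(r$sensitivity, 0.875)
  expect_equal(r$specificity, 0.8)
  expect_equal(r$accuracy, 67 / 80)
  # accuracy is always the count-weighted mean of sensitivity and specificity
  set.seed(20)
  for (i in 1:20) {
    tp <- sample(0:30, 1); np <- tp + sample(0:10, 1)
    tc <- sample(0:30, 1); nc <- tc + sample(0:10, 1)
    if (np == 0 || nc == 0) next
    r <- classification_report(tp, np, tc, nc)
    expect_equal(r$accuracy,
                 (r$sensitivity * np + r$specificity * nc) / (np + nc))
  }
  expect_error(classification_report(5, 4, 1, 2), "exceed")
})

test_that("roc_curve matches exhaustive pair counting", {
  lab <- factor(c("control", "control", "patient", "patient"),
                levels = c("control", "patient"))
  dv <- c(0.1, 0.4, 0.35, 0.8)
  r <- roc_curve(dv, lab)
  expect_equal(r$auc, 0.75)
  expect_equal(r$auc, auc_paircount(dv, lab))
  # random cases, exact agreement with the concordant-pair oracle
  set.seed(21)
  for (i in 1:20) {
    n <- sample(6:25, 1)
    lab <- factor(sample(c("control", "patient"), n, TRUE),
                  levels = c("control", "patient"))
    if (nlevels(droplevels(lab)) < 2) next
    dv <- round(rnorm(n), 1)  # rounding forces some ties
    expect_equal(roc_curve(dv, lab)$auc, auc_paircount(dv, lab))
  }
  # decision values equal to class membership: perfect separation
  lab2 <- factor(rep(c("control", "patient"), each = 10),
                 levels = c("control", "patient"))
  expect_equal(roc_curve(as.numeric(lab2 == "patient"), lab2)$auc, 1)
  set.seed(22)
  expect_lt(abs(roc_curve(rnorm(400), factor(rep(c("control", "patient"), 200),
                                             levels = c("control", "patient")))$auc - 0.5),
            0.1)
  expect_error(roc_curve(1:5, rep("patient", 5)), "both classes")
})

test_that("LOOCV classifies separable synthetic groups perfectly", {
  fx <- make_fixture(n_pat = 8, n_ctl = 8, n_rois = 12, n_planted = 3,
                     shift = 1.25, qol_r = 0.9, seed = 31)
  prm <- selection_params(p_level = 0.05, n_permutations = 100, seed = 2)
  r <- suppressMessages(
    loocv_classify(fx$features, fx$cohort$group, fx$cohort$ndi_qol, prm))
  expect_equal(r$accuracy, 1)
  expect_equal(r$auc, 1)
  expect_equal(r$total_patients, 8)
  expect_equal(r$total_controls, 8)
})

test_that("empty-feature folds fall back to the training majority class", {
  fx <- make_fixture(n_pat = 8, n_ctl = 8, n_rois = 12, n_planted = 2,
                     shift = 0, qol_r = 0, seed = 32)
  # level below the permutation resolution floor: nothing ever selected;
  # the training majority is always the class opposite the held-out subject
  prm <- selection_params(p_level = 1e-4, n_permutations = 100, seed = 2)
  expect_message(
    r <- loocv_classify(fx$features, fx$cohort$group, fx$cohort$ndi_qol, prm),
    "majority")
  expect_length(r$fallback_folds, 16)
  expect_equal(r$accuracy, 0)
})

test_that("stable-mode LOOCV recomputes selection without the held-out subject", {
  fx <- make_fixture(n_pat = 10, n_ctl = 10, n_rois = 12, n_planted = 4,
                     shift = 2, qol_r = 0.9, seed = 33)
  prm <- selection_params(p_level = 0.05, n_permutations = 100, seed = 4)
  r <- suppressMessages(
    loocv_classify(fx$features, fx$cohort$group, fx$cohort$ndi_qol, prm,
                   feature_mode = "stable", tau = 0.9))
  expect_equal(r$accuracy, 1)
  # the leaky global variant exists, clearly separated
  rg <- suppressMessages(
    loocv_classify(fx$features, fx$cohort$group, fx$cohort$ndi_qol, prm,
                   feature_mode = "stable", tau = 0.9,
                   stable_scope = "global"))
  expect_s3_class(rg, "classification_report")
})

test_that("label permutation test bounds and detects real structure", {
  fx <- make_fixture(n_pat = 7, n_ctl = 7, n_rois = 10, n_planted = 3,
                     shift = 1.5, qol_r = 0.9, seed = 41)
  prm <- selection_params(p_level = 0.05, n_permutations = 100, seed = 3)
  pt <- suppressMessages(suppressWarnings(
    permutation_test_accuracy(fx$features, fx$cohort$group, fx$cohort$ndi_qol,
                              prm, n_shuffles = 40, seed = 5)))
  # separable data: real accuracy above every (or almost every) shuffle
  expect_lte(pt$perm_p, 5 / 41)
  expect_equal(pt$real$accuracy, 1)
  expect_length(pt$null_accuracy, 40)
  expect_warning(
    suppressMessages(
      permutation_test_accuracy(fx$features, fx$cohort$group,
                                fx$cohort$ndi_qol, prm, n_shuffles = 5,
                                seed = 6)),
    "coarse null")
})

test_that("replication cohorts are classified once on the stable features", {
  fx <- make_fixture(n_pat = 9, n_ctl = 8, n_rois = 12, n_planted = 3,
                     shift = 1.25, qol_r = 0.9, seed = 51)
  prm <- selection_params(p_level = 0.05, n_permutations = 100, seed = 4)
  fs <- fold_subsets(fx$features, fx$cohort$group, fx$cohort$ndi_qol, prm)
  stab <- stabilize(fs, 0.9)
  expect_gt(nrow(stab), 0)
  # a copy of the training cohort is classified perfectly
  r <- replicate_classify(fx$features, fx$cohort$group, stab,
                          fx$features, fx$cohort$group)
  expect_equal(r$accuracy, 1)
  expect_equal(r$total_patients, 9)
  expect_equal(r$total_controls, 8)
  bad <- data.frame(index = ncol(fx$features) + 1, recurrence = 1)
  expect_error(replicate_classify(fx$features, fx$cohort$group, bad$index,
                                  fx$features[, 1:3], fx$cohort$group),
               "absent")
  expect_error(replicate_classify(fx$features, fx$cohort$group, integer(0),
                                  fx$features, fx$cohort$group), "empty")
})

test_that("fresh replication draws generalize from planted stable features", {
  hits <- vapply(1:10, function(s) {
    coh <- simulate_cohort(12, 12, seed = 6000 + s)
    eff <- default_effects(n_rois = 15, n_planted = 5, group_shift = 0.5,
                           qol_r = 0.65, seed = 6100 + s)
    X <- simulate_edge_data(coh, 15, eff, seed = 6200 + s)
    rep_coh <- simulate_cohort(9, 8, seed = 6300 + s)
    Xr <- simulate_edge_data(rep_coh, 15, eff, seed = 6400 + s)
    stab <- data.frame(index = eff$feature_indices,
                       recurrence = 1)
    r <- replicate_classify(X, coh$group, stab$index, Xr, rep_coh$group)
    r$accuracy >= 0.8
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
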