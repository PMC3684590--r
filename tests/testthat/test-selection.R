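test_that("group_ttest agrees with the reference t-test and handles degeneracy", {
  set.seed(5)
  h <- matrix(rnorm(8 * 20), 8)
  p <- matrix(rnorm(10 * 20, mean = 0.2), 10)
  res <- group_ttest(h, p)
  for (k in c(1, 7, 20)) {
    ref <- t.test(p[, k], h[, k], var.equal = TRUE)
    expect_equal(res$t[k], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p[k], ref$p.value, tolerance = 1e-10)
  }
  # identical groups: t = 0, p = 1 everywhere
  same <- group_ttest(h, h[1:8, ])
  expect_true(all(abs(same$t) < 1e-12))
  expect_true(all(same$p > 1 - 1e-12))
  # a planted 3-sd shift at one edge is overwhelmingly significant
  h2 <- matrix(rnorm(40 * 5), 40); p2 <- matrix(rnorm(40 * 5), 40)
  p2[, 3] <- p2[, 3] + 3
  expect_lt(group_ttest(h2, p2)$p[3], 0.001)
  # constant edge in both groups is flagged, not significant
  h3 <- h; h3[, 2] <- 1; p3 <- p; p3[, 2] <- 1
  res3 <- group_ttest(h3, p3)
  expect_true(res3$degenerate[2])
  expect_true(is.na(res3$p[2]))
  expect_error(group_ttest(h[1, , drop = FALSE], p), "at least 2")
})

test_that("null t-test p-values are approximately uniform", {
  set.seed(6)
  h <- matrix(rnorm(15 * 500), 15)
  p <- matrix(rnorm(15 * 500), 15)
  res <- group_ttest(h, p)
  expect_gt(stats::ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("permutation filter retains by empirical-null rank", {
  set.seed(8)
  h <- matrix(rnorm(12 * 30), 12)
  p <- matrix(rnorm(12 * 30), 12)
  p[, 9] <- p[, 9] + 4  # observed p below every permutation p-value
  B <- 100
  m <- permutation_filter(h, p, p_level = 1 / (B + 1), n_permutations = B,
                          seed = 3)
  expect_true(m[9])
  expect_equal(attr(m, "p_perm")[9], 1 / (B + 1))
  # below the resolution floor nothing survives
  m2 <- permutation_filter(h, p, p_level = 1 / (B + 1) - 1e-6,
                           n_permutations = B, seed = 3)
  expect_false(any(m2))
  # constant edge in both groups is excluded
  h3 <- h; h3[, 2] <- 2; p3 <- p; p3[, 2] <- 2
  m3 <- permutation_filter(h3, p3, p_level = 0.2, n_permutations = B, seed = 4)
  expect_false(m3[2])
})

test_that("permutation filter is calibrated under the null", {
  fracs <- vapply(1:20, function(s) {
    set.seed(700 + s)
    h <- matrix(rnorm(12 * 190), 12)
    p <- matrix(rnorm(12 * 190), 12)
    mean(permutation_filter(h, p, p_level = 0.05, n_permutations = 100,
                            seed = 800 + s))
  }, numeric(1))
  expected <- floor(0.05 * 101) / 101  # attainable retention at this rank rule
  expect_lt(abs(mean(fracs) - expected), 0.02)
})

test_that("QoL correlation filter thresholds two-sided correlation p-values", {
  set.seed(9)
  n <- 20
  qol <- rnorm(n, 75, 10)
  X <- matrix(rnorm(n * 50), n)
  X[, 13] <- 2 - 0.05 * qol  # exact linear function: |r| = 1
  m <- qol_correlation_filter(X, qol, corr_alpha = 1e-12)
  expect_true(m[13])
  expect_true(all(qol_correlation_filter(X, qol, corr_alpha = 1)))
  # p-values agree with cor.test
  pp <- attr(qol_correlation_filter(X, qol, 0.05), "p")
  for (k in c(2, 30)) {
    expect_equal(pp[k], cor.test(X[, k], qol)$p.value, tolerance = 1e-10)
  }
  # retention probability under independence is about corr_alpha
  fr <- vapply(1:20, function(s) {
    set.seed(1200 + s)
    mean(qol_correlation_filter(matrix(rnorm(40 * 200), 40),
                                rnorm(40, 75, 10), 0.05))
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.05), 0.02)
  expect_error(qol_correlation_filter(X, rep(1, n)), "zero variance")
  expect_error(qol_correlation_filter(X[1:3, ], qol[1:3]), "at least 4")
})

test_that("fold subsets honor LOOCV structure and recover strong planted edges", {
  fx <- make_fixture(n_pat = 12, n_ctl = 12, n_rois = 20, n_planted = 2,
                     shift = 0.5, qol_r = 0.85, seed = 3)
  # corr_alpha = 1 isolates the permutation filter's recurrence behaviour
  # (the correlation filter's own calibration is tested above)
  prm <- selection_params(p_level = 0.05, n_permutations = 100,
                          corr_alpha = 1, seed = 7)
  fs <- fold_subsets(fx$features, fx$cohort$group, fx$cohort$ndi_qol, prm)
  expect_s3_class(fs, "fold_subsets")
  expect_length(fs$subsets, 24)
  # deterministic under the same params
  fs2 <- fold_subsets(fx$features, fx$cohort$group, fx$cohort$ndi_qol, prm)
  expect_identical(fs$subsets, fs2$subsets)
  # the held-out subject cannot influence its own fold's subset
  X_tampered <- fx$features
  X_tampered[5, ] <- X_tampered[5, ] + 100
  fs3 <- fold_subsets(X_tampered, fx$cohort$group, fx$cohort$ndi_qol, prm)
  expect_identical(fs$subsets[[5]], fs3$subsets[[5]])
  # strongly planted edges recur in every fold
  rates <- attr(stabilize(fs, 0.5), "rates")
  expect_true(all(fx$effects$feature_indices %in% names(rates)))
  expect_true(all(rates[as.character(fx$effects$feature_indices)] == 1))
  # a vanishing level empties every subset
  prm0 <- selection_params(p_level = 1e-6, n_permutations = 100, seed = 7)
  fs0 <- fold_subsets(fx$features, fx$cohort$group, fx$cohort$ndi_qol, prm0)
  expect_true(all(lengths(fs0$subsets) == 0))
  expect_error(fold_subsets(fx$features[c(1, 13:24), ],
                            fx$cohort$group[c(1, 13:24)],
                            fx$cohort$ndi_qol[c(1, 13:24)], prm),
               "at least 3")
})

test_that("stabilize applies the M/N overlap rule monotonically", {
  # threshold arithmetic: 71 of 80 folds -> rate 0.8875
  subs <- c(replicate(71, c(5L, 9L), simplify = FALSE),
            replicate(9, 5L, simplify = FALSE))
  expect_equal(stabilize(subs, 1.0)$index, 5L)
  expect_false(9L %in% stabilize(subs, 0.90)$index)
  expect_true(9L %in% stabilize(subs, 0.85)$index)
  expect_equal(attr(stabilize(subs, 0.85), "rates")[["9"]], 71 / 80)
  # tau = 1 equals the intersection of all subsets; sizes weakly grow as
  # tau falls (brute-force counting oracle)
  set.seed(10)
  rnd <- replicate(20, sort(sample.int(100, sample(5:30, 1))),
                   simplify = FALSE)
  expect_equal(stabilize(rnd, 1.0)$index,
               sort(Reduce(intersect, rnd)))
  sizes <- vapply(c(1, 0.95, 0.9, 0.85, 0.5), function(tau)
    nrow(stabilize(rnd, tau)), 0L)
  expect_true(all(diff(sizes) >= 0))
  expect_error(stabilize(rnd, 0), "tau")
})

test_that("level sweeps reuse the fold statistics consistently", {
  fx <- make_fixture(n_pat = 10, n_ctl = 10, n_rois = 15, n_planted = 2,
                     shift = 0.6, qol_r = 0.85, seed = 13)
  prm <- selection_params(p_level = 0.05, n_permutations = 100, seed = 5)
  sw <- sweep_p_levels(fx$features, fx$cohort$group, fx$cohort$ndi_qol, prm,
                       levels = c(0.05, 0.01))
  expect_equal(nrow(sw), 2)
  direct <- suppressMessages(
    loocv_classify(fx$features, fx$cohort$group, fx$cohort$ndi_qol, prm))
  expect_equal(sw$accuracy[sw$p_level == 0.05], direct$accuracy)
  sw1 <- sweep_p_levels(fx$features, fx$cohort$group, fx$cohort$ndi_qol, prm,
                        levels = 0.01)
  expect_equal(nrow(sw1), 1)
  expect_error(sweep_p_levels(fx$features, fx$cohort$group,
                              fx$cohort$ndi_qol, prm, levels = c(0.5, 2)),
               "levels")
})
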