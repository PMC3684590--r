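# Standardize with training statistics, fit a libsvm model. Linear kernel and
# C = 1 by default: with edges >> subjects the margin problem is already
# high-dimensional, so a nonlinear kernel adds nothing but variance.
.train_svm <- function(x, y, kernel = "linear", cost = 1,
                       type = "C-classification") {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0] <- 1
  xs <- scale(x, center = mu, scale = sdv)
  fit <- e1071::svm(x = xs, y = y, kernel = kernel, cost = cost,
                    type = type, scale = FALSE)
  list(fit = fit, mu = mu, sd = sdv)
}

# Predict classes and patient-oriented decision values for new rows.
.predict_svm <- function(model, newx) {
  newx <- scale(as.matrix(newx), center = model$mu, scale = model$sd)
  pr <- predict(model$fit, newx, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  lab <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
  dv <- as.numeric(dv[, 1])
  if (lab[1] != "patient") dv <- -dv
  list(class = pr, dv = dv)
}

#' Assemble a classification report from confusion counts
#'
#' Sensitivity is the proportion of patients labeled correctly, specificity
#' the proportion of controls labeled correctly, and accuracy the proportion
#' of all subjects labeled correctly — so accuracy is always the
#' count-weighted mean of sensitivity and specificity. 32/40 controls plus
#' 35/40 patients, for example, give accuracy 67/80 = 0.8375.
#'
#' @param correct_patients,total_patients,correct_controls,total_controls
#'   confusion counts.
#' @param auc area under the ROC curve, if available.
#' @param perm_p label-permutation significance of the accuracy, if available.
#' @return object of class `classification_report`.
#' @export
classification_report <- function(correct_patients, total_patients,
                                  correct_controls, total_controls,
                                  auc = NA_real_, perm_p = NA_real_) {
  if (correct_patients > total_patients || correct_controls > total_controls)
    stop("correct counts exceed totals", call. = FALSE)
  structure(list(
    sensitivity = correct_patients / total_patients,
    specificity = correct_controls / total_controls,
    accuracy = (correct_patients + correct_controls) /
      (total_patients + total_controls),
    correct_patients = correct_patients, total_patients = total_patients,
    correct_controls = correct_controls, total_controls = total_controls,
    auc = auc, perm_p = perm_p
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Sensitivity %d/%d = %.4f | Specificity %d/%d = %.4f | Accuracy %d/%d = %.4f\n",
              x$correct_patients, x$total_patients, x$sensitivity,
              x$correct_controls, x$total_controls, x$specificity,
              x$correct_patients + x$correct_controls,
              x$total_patients + x$total_controls, x$accuracy))
  if (is.finite(x$auc)) cat(sprintf("AUC %.4f\n", x$auc))
  if (is.finite(x$perm_p)) cat(sprintf("Permutation p (accuracy) %.4g\n", x$perm_p))
  invisible(x)
}

# Shared LOOCV engine. feature_fun(k, train) returns the edge indices to use
# for fold k (train = row indices of the training subjects).
.loocv_engine <- function(features, labels, feature_fun, kernel, cost) {
  n <- nrow(features)
  pred <- factor(rep(NA, n), levels = levels(labels))
  dv <- numeric(n)
  fallback <- integer(0)
  for (k in seq_len(n)) {
    train <- setdiff(seq_len(n), k)
    idx <- feature_fun(k, train)
    if (!length(idx)) {
      maj <- names(which.max(table(labels[train])))
      pred[k] <- maj
      dv[k] <- 0
      fallback <- c(fallback, k)
      next
    }
    mod <- .train_svm(features[train, idx, drop = FALSE], labels[train],
                      kernel, cost)
    pr <- .predict_svm(mod, features[k, idx, drop = FALSE])
    pred[k] <- as.character(pr$class)
    dv[k] <- pr$dv
  }
  if (length(fallback))
    message(sprintf("%d fold(s) had an empty feature set; majority-class fallback used",
                    length(fallback)))
  list(pred = pred, dv = dv, fallback = fallback)
}

#' Leave-one-out cross-validated SVM classification
#'
#' Each subject is predicted by a support-vector classifier trained on all
#' other subjects. Features come either from that fold's own selection
#' (`feature_mode = "per_fold"`) or from a stable feature set recomputed on
#' the training subjects only (`feature_mode = "stable"`, overlap threshold
#' `tau` applied to an inner leave-one-out selection — the held-out subject
#' never influences selection). `stable_scope = "global"` instead reuses one
#' stable set computed from all subjects; it leaks the test subject into
#' selection and exists only for comparison. A fold whose feature set is
#' empty falls back to the majority class of its training set (logged).
#'
#' @inheritParams fold_subsets
#' @param feature_mode `"per_fold"` or `"stable"`.
#' @param tau overlap threshold for stable mode.
#' @param stable_scope `"fold"` (default, recomputed per fold) or `"global"`
#'   (leaky single set, for comparison only).
#' @param subsets optional precomputed [fold_subsets()] (reused for per-fold
#'   mode and for the global stable set, e.g. during level sweeps).
#' @param kernel,cost SVM configuration.
#' @return a [classification_report()] with extra fields `predictions`,
#'   `decision_values`, `roc`, `fallback_folds`.
#' @export
loocv_classify <- function(features, labels, qol, params = selection_params(),
                           feature_mode = c("per_fold", "stable"), tau = 0.9,
                           stable_scope = c("fold", "global"), subsets = NULL,
                           kernel = "linear", cost = 1) {
  feature_mode <- match.arg(feature_mode)
  stable_scope <- match.arg(stable_scope)
  features <- as.matrix(features)
  labels <- factor(labels, levels = c("control", "patient"))
  n <- nrow(features)
  if (min(table(labels)) < 3) stop("need at least 3 per class", call. = FALSE)

  if (feature_mode == "per_fold") {
    if (is.null(subsets)) subsets <- fold_subsets(features, labels, qol, params)
    feature_fun <- function(k, train) subsets$subsets[[k]]
  } else if (stable_scope == "global") {
    if (is.null(subsets)) subsets <- fold_subsets(features, labels, qol, params)
    stab <- stabilize(subsets, tau)
    feature_fun <- function(k, train) stab$index
  } else {
    # every outer fold's inner selection excludes a subject pair; compute all
    # unique pair exclusions once, in batched kernel calls
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    excludes <- lapply(seq_len(nrow(pairs)), function(r) as.integer(pairs[r, ]))
    chunk <- max(1L, as.integer(5e4 / params$n_permutations))
    masks <- vector("list", length(excludes))
    for (lo in seq(1, length(excludes), by = chunk)) {
      sel <- lo:min(length(excludes), lo + chunk - 1)
      st <- .fold_statistics(features, labels, qol, params, excludes[sel])
      for (f in seq_along(sel)) {
        masks[[sel[f]]] <- .mask_from_stats(st, f, params$p_level,
                                            params$corr_alpha)
      }
    }
    key <- paste(pairs[, 1], pairs[, 2])
    lookup <- stats::setNames(seq_along(excludes), key)
    feature_fun <- function(k, train) {
      inner <- lapply(train, function(j) {
        masks[[lookup[[paste(min(k, j), max(k, j))]]]]
      })
      stabilize(inner, tau)$index
    }
  }

  res <- .loocv_engine(features, labels, feature_fun, kernel, cost)
  is_pat <- labels == "patient"
  rep <- classification_report(
    sum(res$pred[is_pat] == "patient"), sum(is_pat),
    sum(res$pred[!is_pat] == "control"), sum(!is_pat))
  roc <- if (var(res$dv) > 0) roc_curve(res$dv, labels) else NULL
  rep$auc <- if (is.null(roc)) NA_real_ else roc$auc
  rep$predictions <- res$pred
  rep$decision_values <- res$dv
  rep$roc <- roc
  rep$fallback_folds <- res$fallback
  rep
}

#' ROC curve and AUC from decision values
#'
#' Standard receiver operating characteristic over held-out decision values,
#' with patients as the positive class and larger values indicating
#' "more patient-like" (direction fixed, not data-driven).
#'
#' @param decision_values numeric scores.
#' @param labels factor/character with both classes (`control`, `patient`)
#'   present.
#' @return list of class `roc_curve` with `fpr`, `tpr`, `thresholds`, `auc`.
#' @export
roc_curve <- function(decision_values, labels) {
  labels <- factor(labels, levels = c("control", "patient"))
  if (nlevels(droplevels(labels)) < 2)
    stop("both classes must be present", call. = FALSE)
  r <- pROC::roc(response = labels, predictor = decision_values,
                 levels = c("control", "patient"), direction = "<",
                 quiet = TRUE)
  structure(list(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities),
                 thresholds = rev(r$thresholds), auc = as.numeric(r$auc)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "s", xlab = "1 - specificity",
       ylab = "sensitivity", xlim = c(0, 1), ylim = c(0, 1), ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

#' Label-permutation significance of the LOOCV accuracy
#'
#' Shuffles the subject labels `n_shuffles` times and re-runs the complete
#' pipeline — fold-wise feature selection and LOOCV classification — on each
#' shuffle, forming a null distribution of accuracy. The reported
#' `perm_p = (1 + #{null >= real}) / (1 + n_shuffles)` is significant when the
#' real-label accuracy exceeds the upper 95% point of the null.
#'
#' @inheritParams loocv_classify
#' @param n_shuffles number of label shuffles (a warning is raised below
#'   100; 1000 in the reference analysis).
#' @param seed RNG seed for the shuffles.
#' @return list with `perm_p`, `real` (the real-label
#'   [classification_report()]), and `null_accuracy` (numeric vector).
#' @export
permutation_test_accuracy <- function(features, labels, qol,
                                      params = selection_params(),
                                      n_shuffles = 1000, seed = NULL,
                                      feature_mode = "per_fold", tau = 0.9) {
  if (n_shuffles < 100)
    warning("fewer than 100 label shuffles gives a coarse null")
  labels <- factor(labels, levels = c("control", "patient"))
  real <- loocv_classify(features, labels, qol, params,
                         feature_mode = feature_mode, tau = tau)
  shuffles <- with_seed(seed, {
    lapply(seq_len(n_shuffles), function(b) sample(labels))
  })
  null_acc <- vapply(shuffles, function(lab) {
    suppressMessages(
      loocv_classify(features, lab, qol, params,
                     feature_mode = feature_mode, tau = tau)$accuracy)
  }, numeric(1))
  perm_p <- (1 + sum(null_acc >= real$accuracy)) / (1 + n_shuffles)
  real$perm_p <- perm_p
  list(perm_p = perm_p, real = real, null_accuracy = null_acc)
}

#' Classify an independent replication cohort on the stable features
#'
#' Fits one support-vector classifier on the full training cohort restricted
#' to the stable feature set and applies it once to each replication subject
#' (e.g. the held-back 9 patients + 8 controls).
#'
#' @param train_features,train_labels original cohort.
#' @param stable a [stabilize()] result (must be nonempty).
#' @param test_features,test_labels replication cohort (disjoint subjects).
#' @param kernel,cost SVM configuration.
#' @return a [classification_report()] with `predictions` and
#'   `decision_values` for the replication subjects.
#' @export
replicate_classify <- function(train_features, train_labels, stable,
                               test_features, test_labels,
                               kernel = "linear", cost = 1) {
  idx <- if (inherits(stable, "stable_features")) stable$index else
    as.integer(stable)
  if (!length(idx)) stop("stable feature set is empty", call. = FALSE)
  if (max(idx) > ncol(test_features))
    stop("stable feature index absent from test vectors", call. = FALSE)
  train_labels <- factor(train_labels, levels = c("control", "patient"))
  test_labels <- factor(test_labels, levels = c("control", "patient"))
  mod <- .train_svm(as.matrix(train_features)[, idx, drop = FALSE],
                    train_labels, kernel, cost)
  pr <- .predict_svm(mod, as.matrix(test_features)[, idx, drop = FALSE])
  is_pat <- test_labels == "patient"
  rep <- classification_report(
    sum(pr$class[is_pat] == "patient"), sum(is_pat),
    sum(pr$class[!is_pat] == "control"), sum(!is_pat))
  rep$auc <- if (nlevels(droplevels(test_labels)) == 2 && var(pr$dv) > 0)
    roc_curve(pr$dv, test_labels)$auc else NA_real_
  rep$predictions <- pr$class
  rep$decision_values <- pr$dv
  rep
}
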