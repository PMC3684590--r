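#' Fit the whole-brain connectivity discrimination model
#'
#' The package's central fitter. Given per-subject connectivity feature
#' vectors, group labels and NDI-QoL scores, it runs the fold-wise feature
#' selection (permutation-calibrated group t-test intersected with the
#' QoL-correlation filter, one subset per leave-one-out fold), stabilizes the
#' subsets at each overlap threshold in `tau_list`, and estimates LOOCV
#' classification performance with a linear support-vector machine.
#'
#' @param features subjects x edges matrix (attribute `n_rois` used if
#'   present).
#' @param labels factor with levels control/patient.
#' @param qol per-subject NDI-QoL scores.
#' @param params a [selection_params()].
#' @param tau_list overlap thresholds to stabilize at (reference sweep: 1.00,
#'   0.95, 0.90, 0.85).
#' @param feature_mode `"per_fold"` (each fold classifies on its own subset)
#'   or `"stable"` (per-fold recomputed stable set at each tau; slower).
#' @param kernel,cost SVM configuration.
#' @return object of class `fd_mvpa` with the fold subsets, stable sets and
#'   classification report(s); see [summary.fd_mvpa()].
#' @examples
#' coh <- simulate_cohort(10, 10, seed = 1)
#' eff <- default_effects(n_rois = 20, n_planted = 4, seed = 2)
#' X <- simulate_edge_data(coh, n_rois = 20, effects = eff, seed = 3)
#' fit <- fd_mvpa(X, coh$group, coh$ndi_qol,
#'                selection_params(p_level = 0.05, n_permutations = 100))
#' summary(fit)
#' @export
fd_mvpa <- function(features, labels, qol, params = selection_params(),
                    tau_list = c(1, 0.95, 0.9, 0.85),
                    feature_mode = c("per_fold", "stable"),
                    kernel = "linear", cost = 1) {
  feature_mode <- match.arg(feature_mode)
  features <- as.matrix(features)
  labels <- factor(labels, levels = c("control", "patient"))
  subsets <- fold_subsets(features, labels, qol, params)
  stable <- lapply(tau_list, function(tau) stabilize(subsets, tau))
  names(stable) <- sprintf("tau_%g", tau_list)
  if (feature_mode == "per_fold") {
    report <- loocv_classify(features, labels, qol, params,
                             feature_mode = "per_fold", subsets = subsets,
                             kernel = kernel, cost = cost)
    reports <- NULL
  } else {
    reports <- lapply(tau_list, function(tau) {
      loocv_classify(features, labels, qol, params, feature_mode = "stable",
                     tau = tau, kernel = kernel, cost = cost)
    })
    names(reports) <- names(stable)
    report <- reports[[which.max(vapply(reports, `[[`, 0, "accuracy"))]]
  }
  structure(list(
    call = match.call(), params = params, tau_list = tau_list,
    feature_mode = feature_mode, kernel = kernel, cost = cost,
    subsets = subsets, stable = stable, report = report, reports = reports,
    features = features, labels = labels, qol = qol,
    n_rois = attr(features, "n_rois"), n_edges = ncol(features)
  ), class = "fd_mvpa")
}

#' @export
print.fd_mvpa <- function(x, ...) {
  cat("Whole-brain connectivity discrimination model (fd_mvpa)\n")
  cat(sprintf("  %d subjects (%d controls, %d patients), %d edges\n",
              nrow(x$features), sum(x$labels == "control"),
              sum(x$labels == "patient"), x$n_edges))
  cat(sprintf("  selection: P = %g, %d permutations, corr alpha = %g, seed %d\n",
              x$params$p_level, x$params$n_permutations, x$params$corr_alpha,
              x$params$seed))
  sizes <- vapply(x$stable, nrow, 0L)
  cat(sprintf("  stable set sizes: %s\n",
              paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", ")))
  cat(sprintf("  LOOCV (%s): ", x$feature_mode)); print(x$report)
  invisible(x)
}

#' Summarize a fitted connectivity discrimination model
#'
#' @param object an [fd_mvpa()] fit.
#' @param ... unused.
#' @return the object, invisibly, after printing stable-set sizes per overlap
#'   threshold and the classification report(s).
#' @export
summary.fd_mvpa <- function(object, ...) {
  print(object)
  if (!is.null(object$reports)) {
    cat("Per-threshold stable-mode LOOCV:\n")
    for (nm in names(object$reports)) {
      cat(sprintf("  %s: ", nm)); print(object$reports[[nm]])
    }
  }
  invisible(object)
}

#' Recurrence rates of the selected edges
#'
#' @param object an [fd_mvpa()] fit.
#' @param tau optional overlap threshold; if given, only edges in that stable
#'   set are returned.
#' @param ... unused.
#' @return named numeric vector of recurrence rates (names = edge indices).
#' @export
coef.fd_mvpa <- function(object, tau = NULL, ...) {
  rates <- attr(object$stable[[1]], "rates")
  if (!is.null(tau)) rates <- rates[rates >= tau - 1e-9]
  sort(rates, decreasing = TRUE)
}

#' Predict group membership for new subjects
#'
#' Trains the final support-vector classifier on the full fitted cohort
#' restricted to the stable feature set at `tau` and applies it to the new
#' feature vectors (replication-cohort evaluation).
#'
#' @param object an [fd_mvpa()] fit.
#' @param newdata subjects x edges matrix with the same edge dimension.
#' @param tau overlap threshold selecting the stable set to use.
#' @param ... unused.
#' @return factor of predicted labels with attribute `decision_values`.
#' @export
predict.fd_mvpa <- function(object, newdata, tau = 0.9, ...) {
  stab <- stabilize(object$subsets, tau)
  if (!nrow(stab)) stop("stable feature set is empty at this tau", call. = FALSE)
  mod <- .train_svm(object$features[, stab$index, drop = FALSE],
                    object$labels, object$kernel, object$cost)
  pr <- .predict_svm(mod, as.matrix(newdata)[, stab$index, drop = FALSE])
  structure(pr$class, decision_values = pr$dv)
}

#' Plot a fitted connectivity discrimination model
#'
#' Left panel: stable-set size against the overlap threshold (weakly
#' decreasing in tau). Right panel: the LOOCV ROC curve if available,
#' otherwise the recurrence-rate histogram.
#'
#' @param x an [fd_mvpa()] fit.
#' @param ... passed to the underlying plot calls.
#' @export
plot.fd_mvpa <- function(x, ...) {
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  sizes <- vapply(x$stable, nrow, 0L)
  plot(x$tau_list, sizes, type = "b", xlab = "overlap threshold tau",
       ylab = "stable features", ...)
  if (!is.null(x$report$roc)) {
    plot(x$report$roc, main = sprintf("LOOCV ROC (AUC %.3f)", x$report$auc))
  } else {
    hist(attr(x$stable[[1]], "rates"), main = "recurrence rates",
         xlab = "M/N")
  }
  invisible(x)
}

#' Sweep the selection significance level
#'
#' Re-runs LOOCV classification over a grid of permutation-filter levels
#' (reference range 0.05 down to 0.00001). The per-fold permutation nulls and
#' correlation p-values are computed once and re-thresholded per level, so
#' the sweep costs one selection pass plus the SVM fits.
#'
#' @inheritParams fd_mvpa
#' @param levels significance levels to evaluate, all in (0, 1).
#' @return data.frame `p_level`, `accuracy`, `sensitivity`, `specificity`,
#'   `mean_features`, with attribute `best` (the argmax level).
#' @export
sweep_p_levels <- function(features, labels, qol, params = selection_params(),
                           levels = c(0.05, 0.01, 0.001, 1e-4, 1e-5),
                           kernel = "linear", cost = 1) {
  if (any(levels <= 0 | levels >= 1)) stop("levels must be in (0,1)", call. = FALSE)
  features <- as.matrix(features)
  labels <- factor(labels, levels = c("control", "patient"))
  n <- nrow(features)
  # the permutation null does not depend on the level, so one statistics
  # pass serves every level in the sweep
  stats <- .fold_statistics(features, labels, qol, params)
  rows <- lapply(levels, function(lv) {
    subs <- lapply(seq_len(n), function(k) {
      .mask_from_stats(stats, k, lv, params$corr_alpha)
    })
    fs <- structure(list(subsets = subs, n_folds = n,
                         n_edges = ncol(features), params = params),
                    class = "fold_subsets")
    rep <- suppressMessages(
      loocv_classify(features, labels, qol, params, feature_mode = "per_fold",
                     subsets = fs, kernel = kernel, cost = cost))
    data.frame(p_level = lv, accuracy = rep$accuracy,
               sensitivity = rep$sensitivity, specificity = rep$specificity,
               mean_features = mean(lengths(subs)))
  })
  out <- do.call(rbind, rows)
  attr(out, "best") <- out$p_level[which.max(out$accuracy)]
  out
}
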