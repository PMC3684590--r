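#' Leave-one-out support-vector regression of a clinical score
#'
#' Predicts each patient's clinical score from their connectivity features
#' restricted to the stable abnormal edges, by epsilon-insensitive linear
#' support-vector regression trained on the remaining patients
#' (leave-one-out, so every prediction is out-of-fold).
#'
#' @param features patients x edges matrix.
#' @param targets numeric score per patient (must not be constant).
#' @param stable a [stabilize()] result or integer vector of edge indices.
#' @param kernel,cost SVR configuration.
#' @return numeric vector of out-of-fold predictions, one per patient.
#' @export
predict_scores <- function(features, targets, stable,
                           kernel = "linear", cost = 1) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 5) stop("need at least 5 patients", call. = FALSE)
  if (length(targets) != n) stop("targets length mismatch", call. = FALSE)
  if (sd(targets) == 0) stop("constant target score", call. = FALSE)
  idx <- if (inherits(stable, "stable_features")) stable$index else
    as.integer(stable)
  if (!length(idx)) stop("stable feature set is empty", call. = FALSE)
  x <- features[, idx, drop = FALSE]
  vapply(seq_len(n), function(k) {
    mod <- .train_svm(x[-k, , drop = FALSE], targets[-k], kernel, cost,
                      type = "eps-regression")
    newx <- scale(x[k, , drop = FALSE], center = mod$mu, scale = mod$sd)
    as.numeric(predict(mod$fit, newx))
  }, numeric(1))
}

#' Relative prediction error
#'
#' Elementwise `|predicted - actual| / |actual|`. Entries with `actual == 0`
#' are undefined and returned as `NA` (exclude them from means).
#'
#' @param predicted,actual numeric vectors of equal length.
#' @return numeric vector of per-subject relative errors.
#' @export
relative_error <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("length mismatch", call. = FALSE)
  out <- abs(predicted - actual) / abs(actual)
  out[actual == 0] <- NA_real_
  out
}

#' Connectivity severity index from predicted NDI-QoL
#'
#' Normalizes each patient's (out-of-fold) predicted NDI-QoL by the
#' patient-group mean prediction, so the mean CSI is exactly 1.0. Lower CSI
#' means more severe illness.
#'
#' @param predicted_qol numeric predictions for >= 2 patients with nonzero
#'   mean.
#' @return numeric CSI vector (mean exactly 1 up to float tolerance).
#' @export
compute_csi <- function(predicted_qol) {
  if (length(predicted_qol) < 2) stop("need at least 2 patients", call. = FALSE)
  m <- mean(predicted_qol)
  if (m == 0) stop("mean predicted QoL is zero", call. = FALSE)
  predicted_qol / m
}

#' Per-patient severity table
#'
#' Runs the severity stage end to end for the patients of a cohort: LOO-SVR
#' prediction of NDI-QoL from the stable abnormal edges, conversion to the
#' connectivity severity index, and the actual clinical scores side by side.
#'
#' @param cohort cohort data.frame (see [simulate_cohort()]); only patients
#'   enter the table.
#' @param features subjects x edges matrix aligned with `cohort` rows.
#' @param stable stable feature set.
#' @param kernel,cost SVR configuration.
#' @return data.frame of class `csi_table`: `subject_id`, `predicted_qol`,
#'   `csi`, `ndi_qol`, `ndi_symptom`, `sds`, `sas`, `duration_months`,
#'   `age_years`.
#' @export
csi_table <- function(cohort, features, stable, kernel = "linear", cost = 1) {
  pat <- cohort$group == "patient"
  pred <- predict_scores(as.matrix(features)[pat, , drop = FALSE],
                         cohort$ndi_qol[pat], stable, kernel, cost)
  out <- data.frame(
    subject_id = cohort$subject_id[pat],
    predicted_qol = pred,
    csi = compute_csi(pred),
    ndi_qol = cohort$ndi_qol[pat],
    ndi_symptom = cohort$ndi_symptom[pat],
    sds = cohort$sds[pat],
    sas = cohort$sas[pat],
    duration_months = cohort$duration_months[pat],
    age_years = cohort$age_years[pat]
  )
  structure(out, class = c("csi_table", "data.frame"))
}

#' Pearson and partial Pearson correlation
#'
#' Partial correlation of `x` and `y` given covariates, computed from the
#' inverse correlation matrix; the two-sided p-value uses `n - 2 - k` degrees
#' of freedom for `k` covariates. With no covariates this is the plain
#' Pearson correlation test.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric matrix/data.frame of covariates.
#' @return list with `r`, `p`, `df`.
#' @export
partial_cor <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("length mismatch", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("constant variable", call. = FALSE)
  if (is.null(covariates) || NCOL(covariates) == 0) {
    k <- 0
    r <- cor(x, y)
  } else {
    z <- as.matrix(covariates)
    if (any(apply(z, 2, sd) == 0)) stop("constant covariate", call. = FALSE)
    k <- ncol(z)
    C <- cor(cbind(x, y, z))
    P <- solve(C)
    r <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  }
  df <- n - 2 - k
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(tstat), df), df = df)
}

#' Correlations between the CSI and clinical measures
#'
#' For each clinical score, the plain Pearson correlation with the CSI and
#' the partial correlation controlling for the other scores named in
#' `control_for` (the score itself is never its own covariate). The default
#' reproduces the reference analysis: the CSI-symptom association is
#' controlled for SDS and SAS, while SDS and SAS are controlled for the NDI
#' symptom score.
#'
#' @param csi_tab a [csi_table()].
#' @param variables clinical columns to correlate with the CSI.
#' @param control_for covariate pool; per variable the covariates are
#'   `setdiff(control_for, variable)`.
#' @return data.frame `variable`, `r`, `p`, `partial_r`, `partial_p`,
#'   `covariates`.
#' @export
csi_correlations <- function(csi_tab,
                             variables = c("ndi_symptom", "sds", "sas",
                                           "duration_months"),
                             control_for = c("ndi_symptom", "sds", "sas")) {
  if (nrow(csi_tab) < 5) stop("need at least 5 patients", call. = FALSE)
  rows <- lapply(variables, function(v) {
    plain <- partial_cor(csi_tab$csi, csi_tab[[v]])
    covs <- setdiff(control_for, v)
    partial <- if (length(covs)) {
      partial_cor(csi_tab$csi, csi_tab[[v]],
                  csi_tab[, covs, drop = FALSE])
    } else plain
    data.frame(variable = v, r = plain$r, p = plain$p,
               partial_r = partial$r, partial_p = partial$p,
               covariates = paste(covs, collapse = "+"))
  })
  do.call(rbind, rows)
}

#' Per-edge partial correlation with NDI-QoL controlling for age
#'
#' For each stable abnormal edge, the partial Pearson correlation between the
#' edge's connectivity values and NDI-QoL across subjects, controlling for
#' age. The sign of this correlation drives the network report's sign split.
#'
#' @param features subjects x edges matrix.
#' @param qol,age numeric vectors over the same subjects.
#' @param indices edge indices to evaluate (e.g. `stable$index`).
#' @return data.frame `index`, `r`, `p`.
#' @export
edge_qol_partial_corr <- function(features, qol, age, indices) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(qol) != n || length(age) != n)
    stop("qol/age must match rows of features", call. = FALSE)
  if (sd(qol) == 0) stop("constant qol", call. = FALSE)
  indices <- as.integer(indices)
  # residualize on age once (constant age degenerates to plain correlation)
  design <- if (sd(age) > 0) cbind(1, age) else cbind(rep(1, n))
  k <- ncol(design) - 1
  qd <- qr(design)
  rq <- qr.resid(qd, qol)
  rx <- qr.resid(qd, features[, indices, drop = FALSE])
  r <- suppressWarnings(as.vector(cor(rq, rx)))
  df <- n - 2 - k
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  data.frame(index = indices, r = r, p = 2 * pt(-abs(tstat), df))
}
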