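#' Linear detrend and band-pass filter ROI time series
#'
#' Removes the per-column linear trend, then band-pass filters each column to
#' `[low_hz, high_hz]` (default 0.01-0.08 Hz, the conventional resting-state
#' band that suppresses scanner drift below and physiological noise above).
#' The default realization is an ideal frequency-domain mask: DFT bins with
#' two-sided frequency outside the band are zeroed. A 4th-order Butterworth
#' filter applied forwards and backwards (`signal::filtfilt`, zero phase) is
#' available as `method = "butterworth"`.
#'
#' @param ts `T x R` numeric matrix (timepoints x regions).
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1 / (2 * tr_seconds)`.
#' @param tr_seconds repetition time in seconds (taken from
#'   `attr(ts, "tr_seconds")` if absent).
#' @param method `"fft"` (ideal mask) or `"butterworth"`.
#' @return the conditioned matrix, same shape, `tr_seconds` attribute kept.
#' @export
detrend_bandpass <- function(ts, low_hz = 0.01, high_hz = 0.08,
                             tr_seconds = attr(ts, "tr_seconds"),
                             method = c("fft", "butterworth")) {
  method <- match.arg(method)
  ts <- as.matrix(ts)
  if (is.null(tr_seconds)) stop("tr_seconds must be supplied", call. = FALSE)
  nyq <- 1 / (2 * tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop(sprintf("band must satisfy 0 < low < high < Nyquist (%g Hz)", nyq),
         call. = FALSE)
  }
  T <- nrow(ts)
  tt <- seq_len(T)
  # exact removal of per-column linear trend (including the mean)
  fit <- stats::lm.fit(cbind(1, tt), ts)
  x <- as.matrix(fit$residuals)
  if (method == "fft") {
    f <- (tt - 1) / (T * tr_seconds)
    f <- pmin(f, 1 / tr_seconds - f)
    keep <- f >= low_hz & f <= high_hz
    X <- stats::mvfft(x)
    X[!keep, ] <- 0
    out <- Re(stats::mvfft(X, inverse = TRUE)) / T
  } else {
    bf <- signal::butter(4, c(low_hz, high_hz) / nyq, type = "pass")
    out <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  }
  dimnames(out) <- dimnames(ts)
  attr(out, "tr_seconds") <- tr_seconds
  out
}

#' Regress nuisance signals out of ROI time series
#'
#' Ordinary least squares of every ROI column on an intercept plus the given
#' nuisance regressors (e.g. white-matter, CSF, ventricle and motion summary
#' signals), returning the residuals. Global signal regression is deliberately
#' not part of the model and no global regressor is added. If the design is
#' rank deficient a warning is raised and the Moore-Penrose pseudo-inverse fit
#' is used.
#'
#' @param ts `T x R` matrix.
#' @param regressors `T x K` matrix of nuisance signals, or `NULL` for
#'   intercept-only (mean removal).
#' @return residual matrix, orthogonal to the intercept and every regressor.
#' @export
regress_nuisance <- function(ts, regressors = NULL) {
  ts <- as.matrix(ts)
  T <- nrow(ts)
  design <- cbind(intercept = rep(1, T), regressors)
  if (ncol(design) >= T) stop("more regressors than timepoints", call. = FALSE)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    warning("rank-deficient nuisance design; using pseudo-inverse fit")
    sv <- svd(design)
    pos <- sv$d > max(sv$d) * 1e-12
    beta <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) %*% ts / sv$d[pos])
    out <- ts - design %*% beta
  } else {
    out <- qr.resid(qrd, ts)
  }
  dimnames(out) <- dimnames(ts)
  attr(out, "tr_seconds") <- attr(ts, "tr_seconds")
  out
}

#' Vectorized Fisher-z functional connectivity
#'
#' Pearson-correlates every pair of ROI columns, applies Fisher's r-to-z
#' transform `atanh(r)`, and linearizes the strict upper triangle of the
#' symmetric matrix in the [edge_index()] order. With 1024 regions this yields
#' the 523776-dimensional feature vector. Correlations with `|r| >= 1 - 1e-12`
#' (degenerate, e.g. duplicated columns) are clipped to that bound with a
#' warning before the transform so the features stay finite.
#'
#' @param ts conditioned `T x R` matrix; every column must have nonzero
#'   variance (a zero-variance ROI raises an error naming it).
#' @return numeric vector of length `R(R-1)/2` with attribute `n_rois`.
#' @export
connectivity_vector <- function(ts) {
  ts <- as.matrix(ts)
  sds <- apply(ts, 2, sd)
  if (any(sds == 0)) {
    stop(sprintf("ROI(s) with zero variance: %s",
                 paste(which(sds == 0), collapse = ", ")), call. = FALSE)
  }
  R <- ncol(ts)
  r <- cor(ts)
  v <- r[edge_pairs(R)]
  clip <- abs(v) >= 1 - 1e-12
  if (any(clip)) {
    warning(sprintf("%d edge correlation(s) clipped at |r| = 1 - 1e-12", sum(clip)))
    v[clip] <- sign(v[clip]) * (1 - 1e-12)
  }
  z <- atanh(v)
  attr(z, "n_rois") <- R
  z
}

#' Condition a cohort of time series and build the feature matrix
#'
#' Applies [detrend_bandpass()], optional [regress_nuisance()], and
#' [connectivity_vector()] to each subject's time-series matrix.
#'
#' @param ts_list named list of `T x R` matrices (one per subject).
#' @param low_hz,high_hz,method passed to [detrend_bandpass()].
#' @param regressors `NULL`, one `T x K` matrix shared by all subjects, or a
#'   list of per-subject matrices.
#' @return subjects x edges feature matrix with attribute `n_rois`.
#' @export
cohort_connectivity <- function(ts_list, low_hz = 0.01, high_hz = 0.08,
                                regressors = NULL, method = "fft") {
  rows <- lapply(seq_along(ts_list), function(s) {
    x <- detrend_bandpass(ts_list[[s]], low_hz, high_hz, method = method)
    reg <- if (is.list(regressors)) regressors[[s]] else regressors
    x <- regress_nuisance(x, reg)
    connectivity_vector(x)
  })
  X <- do.call(rbind, rows)
  rownames(X) <- names(ts_list)
  attr(X, "n_rois") <- ncol(ts_list[[1]])
  X
}
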