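#' Planted abnormal-connection effects
#'
#' Describes the sparse set of edges whose Fisher-z connectivity is simulated
#' to differ between patients and controls and to covary with the patients'
#' quality-of-life (NDI-QoL) score. `group_shift` is the patient-minus-control
#' difference in mean z at each planted edge; `qol_slope` is the within-patient
#' linear coefficient of the edge value on (centered) NDI-QoL, so its sign is
#' the sign of the planted edge-QoL correlation; `noise_sd` is the standard
#' deviation of the subject-level edge noise shared by all edges.
#'
#' @param feature_indices distinct linear edge indices (see [edge_index()]);
#'   may be empty for a null cohort.
#' @param group_shift numeric, recycled to `length(feature_indices)`.
#' @param qol_slope numeric, recycled likewise (units: z per QoL point).
#' @param noise_sd positive scalar.
#' @return an object of class `planted_effects`.
#' @seealso [default_effects()] for a ready-made configuration.
#' @export
planted_effects <- function(feature_indices = integer(0), group_shift = 0,
                            qol_slope = 0, noise_sd = 0.25) {
  feature_indices <- as.integer(feature_indices)
  if (anyDuplicated(feature_indices)) stop("planted indices must be distinct", call. = FALSE)
  if (any(feature_indices < 1)) stop("planted indices must be >= 1", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  k <- length(feature_indices)
  structure(list(
    feature_indices = feature_indices,
    group_shift = rep_len(as.numeric(group_shift), k),
    qol_slope = rep_len(as.numeric(qol_slope), k),
    noise_sd = as.numeric(noise_sd)
  ), class = "planted_effects")
}

#' Default planted-effect configuration
#'
#' Draws `n_planted` distinct edges with a patient-vs-control shift of
#' `2 * noise_sd` and a within-patient edge-QoL correlation of magnitude
#' `qol_r`, of which a fraction `frac_negative` (default 65%, the sign split
#' reported for the abnormal dyspepsia network) are negative. The slope per
#' QoL point is back-computed from the target correlation assuming a patient
#' QoL standard deviation of `qol_sd` (about 10 points in the reference
#' cohort).
#'
#' @param n_rois number of regions.
#' @param n_planted number of abnormal edges.
#' @param group_shift mean z difference patients minus controls.
#' @param qol_r target |correlation| between planted edge values and NDI-QoL
#'   within patients.
#' @param frac_negative fraction of planted edges with negative QoL slope.
#' @param noise_sd edge noise SD.
#' @param qol_sd assumed patient QoL standard deviation used to convert the
#'   target correlation into a raw slope.
#' @param seed RNG seed for the edge draw.
#' @return a [planted_effects()] object.
#' @export
default_effects <- function(n_rois = 90, n_planted = 10,
                            group_shift = 2 * noise_sd, qol_r = 0.65,
                            frac_negative = 0.65, noise_sd = 0.25,
                            qol_sd = 10, seed = NULL) {
  E <- n_edges(n_rois)
  stopifnot_scalar_count(n_planted, "n_planted", min = 1)
  if (n_planted > E) stop("more planted edges than edges", call. = FALSE)
  with_seed(seed, {
    idx <- sort(sample.int(E, n_planted))
    n_neg <- round(frac_negative * n_planted)
    signs <- sample(c(rep(-1, n_neg), rep(1, n_planted - n_neg)))
  })
  slope <- signs * (qol_r / sqrt(1 - qol_r^2)) * noise_sd / qol_sd
  planted_effects(idx, group_shift = group_shift, qol_slope = slope,
                  noise_sd = noise_sd)
}

#' Clinical-score generating model
#'
#' Group-wise means and SDs (defaults follow the reference cohort: patients
#' have NDI-QoL 76.65 +/- 10.17, NDI symptom 47.2 +/- 15.87, SDS 44.4 +/- 10.0,
#' SAS 42.6 +/- 7.2, duration 37.8 +/- 28.2 months; controls 87.41 +/- 5.44,
#' 1.23 +/- 1.90, 33.9 +/- 5.8, 32.3 +/- 5.9) plus factor loadings of a shared
#' latent "severity" trait. The loadings induce the observed covariance
#' pattern: NDI symptom score correlates positively with SDS and SAS, NDI-QoL
#' loads negatively, and disease duration is independent of everything.
#'
#' @param patient,control named lists of `c(mean, sd)` pairs for
#'   `ndi_qol`, `ndi_symptom`, `sds`, `sas`, `age_years` and (patients only)
#'   `duration_months`.
#' @param loadings named numeric loadings on the latent severity factor.
#' @return a list of class `score_model`.
#' @export
score_model <- function(
    patient = list(ndi_qol = c(76.6503, 10.1738), ndi_symptom = c(47.2, 15.8668),
                   sds = c(44.375, 9.9799), sas = c(42.625, 7.1712),
                   duration_months = c(37.825, 28.2197), age_years = c(22.45, 1.8529)),
    control = list(ndi_qol = c(87.4057, 5.4378), ndi_symptom = c(1.225, 1.9012),
                   sds = c(33.925, 5.7708), sas = c(32.3, 5.8713),
                   age_years = c(22.925, 1.5256)),
    loadings = c(ndi_qol = -0.6, ndi_symptom = 0.8, sds = 0.55, sas = 0.55)) {
  structure(list(patient = patient, control = control, loadings = loadings),
            class = "score_model")
}

.draw_scores <- function(n, pars, loadings) {
  latent <- rnorm(n)
  draw <- function(name) {
    p <- pars[[name]]
    lam <- if (name %in% names(loadings)) loadings[[name]] else 0
    p[1] + p[2] * (lam * latent + sqrt(1 - lam^2) * rnorm(n))
  }
  out <- data.frame(
    ndi_qol = pmin(100, pmax(0, draw("ndi_qol"))),
    ndi_symptom = pmax(0, draw("ndi_symptom")),
    sds = pmax(0, draw("sds")),
    sas = pmax(0, draw("sas")),
    duration_months = if ("duration_months" %in% names(pars)) {
      pmax(0, pars$duration_months[1] + pars$duration_months[2] * rnorm(n))
    } else NA_real_,
    age_years = draw("age_years")
  )
  out
}

#' Simulate a case-control cohort with clinical scores
#'
#' Generates `n_patients` functional-dyspepsia-like patients and `n_controls`
#' healthy controls with subject IDs, group labels and clinical scores drawn
#' from [score_model()]. In expectation patients score lower on NDI-QoL and
#' higher on the NDI symptom checklist, SDS and SAS than controls; within each
#' group the symptom score correlates positively with SDS and SAS through the
#' latent severity factor, while disease duration (patients only) is
#' independent of every other score.
#'
#' @param n_patients,n_controls group sizes (>= 2 each).
#' @param model a [score_model()].
#' @param seed RNG seed; fixing it fixes the cohort.
#' @return a data.frame with columns `subject_id`, `group`
#'   (factor control/patient), `ndi_qol`, `ndi_symptom`, `sds`, `sas`,
#'   `duration_months` (NA for controls) and `age_years`.
#' @examples
#' coh <- simulate_cohort(40, 40, seed = 1)
#' tapply(coh$ndi_qol, coh$group, mean)
#' @export
simulate_cohort <- function(n_patients, n_controls, model = score_model(),
                            seed = NULL) {
  stopifnot_scalar_count(n_patients, "n_patients", min = 2)
  stopifnot_scalar_count(n_controls, "n_controls", min = 2)
  with_seed(seed, {
    pat <- .draw_scores(n_patients, model$patient, model$loadings)
    ctl <- .draw_scores(n_controls, model$control, model$loadings)
  })
  pat$duration_months[!is.finite(pat$duration_months)] <- 0
  ctl$duration_months <- NA_real_
  out <- rbind(
    cbind(subject_id = sprintf("FD%03d", seq_len(n_patients)),
          group = "patient", pat),
    cbind(subject_id = sprintf("HC%03d", seq_len(n_controls)),
          group = "control", ctl)
  )
  out$group <- factor(out$group, levels = c("control", "patient"))
  rownames(out) <- NULL
  out
}

#' Simulate an ROI atlas
#'
#' Random region centroids (mm, a brain-sized bounding box in a single
#' MNI-like coordinate convention) with cortical-system labels drawn from the
#' five systems used by the network report.
#'
#' @param n_rois number of regions (>= 3).
#' @param seed RNG seed.
#' @return data.frame with `roi_id`, `x_mm`, `y_mm`, `z_mm`, `system`.
#' @export
simulate_atlas <- function(n_rois = 90, seed = NULL) {
  stopifnot_scalar_count(n_rois, "n_rois", min = 3)
  systems <- c("limbic_paralimbic", "prefrontal", "tempo_parietal", "visual", "other")
  with_seed(seed, {
    out <- data.frame(
      roi_id = seq_len(n_rois),
      x_mm = runif(n_rois, -70, 70),
      y_mm = runif(n_rois, -105, 70),
      z_mm = runif(n_rois, -45, 75),
      system = sample(systems, n_rois, replace = TRUE,
                      prob = c(0.25, 0.2, 0.25, 0.15, 0.15))
    )
  })
  out
}

#' Simulate per-subject connectivity feature vectors directly
#'
#' Draws each subject's length `R(R-1)/2` Fisher-z edge vector from a shared
#' per-edge baseline plus Gaussian noise. At the planted edges patients
#' additionally receive the group shift and a term proportional to their
#' (patient-mean-centered) NDI-QoL, so the planted edges differ in group mean
#' by `group_shift` and correlate with QoL within patients with the sign of
#' `qol_slope`. All other edges are pure noise. This is the default, fast path
#' for exercising feature selection without time-series simulation.
#'
#' @param cohort a cohort from [simulate_cohort()].
#' @param n_rois number of regions.
#' @param effects a [planted_effects()] object.
#' @param seed RNG seed.
#' @return numeric matrix, subjects x edges, with `rownames` the subject IDs
#'   and attribute `n_rois`.
#' @export
simulate_edge_data <- function(cohort, n_rois = 90,
                               effects = planted_effects(), seed = NULL) {
  E <- n_edges(n_rois)
  if (length(effects$feature_indices) && max(effects$feature_indices) > E) {
    stop("planted index out of range for n_rois", call. = FALSE)
  }
  n <- nrow(cohort)
  pat <- cohort$group == "patient"
  with_seed(seed, {
    baseline <- rnorm(E, mean = 0.3, sd = 0.15)
    X <- matrix(rnorm(n * E, sd = effects$noise_sd), n, E, byrow = TRUE)
  })
  X <- sweep(X, 2, baseline, "+")
  if (length(effects$feature_indices)) {
    qolc <- cohort$ndi_qol - mean(cohort$ndi_qol[pat])
    for (m in seq_along(effects$feature_indices)) {
      k <- effects$feature_indices[m]
      X[pat, k] <- X[pat, k] + effects$group_shift[m] +
        effects$qol_slope[m] * qolc[pat]
    }
  }
  rownames(X) <- cohort$subject_id
  attr(X, "n_rois") <- n_rois
  X
}

# Unit-variance band-limited noise columns (T x R) on a TR grid.
.bandlimited_noise <- function(t_points, n_cols, tr_seconds, low_hz, high_hz) {
  w <- matrix(rnorm(t_points * n_cols), t_points, n_cols)
  f <- (seq_len(t_points) - 1) / (t_points * tr_seconds)
  f <- pmin(f, 1 / tr_seconds - f)  # two-sided frequency
  keep <- f >= low_hz & f <= high_hz
  W <- stats::mvfft(w)
  W[!keep, ] <- 0
  x <- Re(stats::mvfft(W, inverse = TRUE)) / t_points
  scale(x, center = TRUE, scale = apply(x, 2, sd))
}

#' Simulate ROI time series realizing planted connectivity effects
#'
#' Generates one `t_points x n_rois` matrix per subject: band-limited
#' (0.01-0.08 Hz) latent signals, pairwise mixed at the planted edges so that
#' the post-conditioning Pearson correlation approximates `tanh(z)` with `z`
#' the subject's planted Fisher-z value (group shift plus QoL coupling for
#' patients, 0 for controls), plus a random linear drift and out-of-band
#' contamination (a 0.15 Hz tone and white noise) so that detrending,
#' band-pass filtering and nuisance handling are genuinely exercised.
#' Planted edges must be vertex-disjoint because correlations are induced by
#' mixing the two member signals of each pair.
#'
#' A 6-minute session at TR = 2 s yields 180 volumes; conventionally the
#' first 10 are discarded before conditioning (see [session_volumes()]).
#'
#' @inheritParams simulate_edge_data
#' @param atlas atlas data.frame (its row count fixes the number of regions).
#' @param t_points timepoints per subject (> 20).
#' @param tr_seconds repetition time in seconds.
#' @param drift_amplitude SD of the per-column linear drift total excursion.
#' @param outband_amplitude amplitude of the out-of-band contamination.
#' @return named list of `t_points x n_rois` matrices, one per subject, each
#'   with attribute `tr_seconds`.
#' @export
simulate_timeseries <- function(cohort, atlas, effects = planted_effects(),
                                t_points = 180, tr_seconds = 2, seed = NULL,
                                drift_amplitude = 1, outband_amplitude = 1) {
  stopifnot_scalar_count(t_points, "t_points", min = 21)
  n_rois <- nrow(atlas)
  idx <- effects$feature_indices
  if (length(idx)) {
    if (max(idx) > n_edges(n_rois)) stop("planted index out of range", call. = FALSE)
    prs <- edge_pair(idx, n_rois)
    if (anyDuplicated(c(prs))) {
      stop("time-series simulation requires vertex-disjoint planted edges", call. = FALSE)
    }
  }
  pat <- cohort$group == "patient"
  qolc <- cohort$ndi_qol - mean(cohort$ndi_qol[pat])
  tt <- seq_len(t_points)
  with_seed(seed, {
    out <- lapply(seq_len(nrow(cohort)), function(s) {
      x <- .bandlimited_noise(t_points, n_rois, tr_seconds, 0.01, 0.08)
      if (length(idx) && pat[s]) {
        z <- effects$group_shift + effects$qol_slope * qolc[s]
        rho <- tanh(z)
        for (m in seq_along(idx)) {
          i <- prs[m, 1]; j <- prs[m, 2]
          x[, j] <- rho[m] * x[, i] + sqrt(1 - rho[m]^2) * x[, j]
        }
      }
      drift <- outer(tt / t_points, rnorm(n_rois, sd = drift_amplitude))
      tone <- outband_amplitude *
        sin(2 * pi * 0.15 * tt * tr_seconds + runif(1, 0, 2 * pi))
      m <- x + drift + tone + matrix(rnorm(t_points * n_rois, sd = 0.2 * outband_amplitude),
                                     t_points, n_rois)
      attr(m, "tr_seconds") <- tr_seconds
      m
    })
  })
  names(out) <- cohort$subject_id
  out
}

#' Session volume bookkeeping
#'
#' Number of whole-brain volumes acquired in a resting-state session and the
#' number retained after discarding initial non-equilibrium volumes. The
#' reference acquisition (6 minutes at TR = 2 s, first 10 volumes dropped)
#' gives 180 acquired and 170 retained.
#'
#' @param duration_min session length in minutes.
#' @param tr_seconds repetition time in seconds.
#' @param n_discard initial volumes discarded.
#' @return list with `acquired` and `retained` counts.
#' @export
session_volumes <- function(duration_min = 6, tr_seconds = 2, n_discard = 10) {
  acquired <- as.integer(round(duration_min * 60 / tr_seconds))
  list(acquired = acquired, retained = acquired - as.integer(n_discard))
}

#' Drop initial volumes from a time-series matrix
#'
#' @param ts a `T x R` matrix.
#' @param n_discard leading rows to drop.
#' @return the trimmed matrix.
#' @export
discard_initial <- function(ts, n_discard = 10) {
  if (n_discard >= nrow(ts)) stop("cannot discard all volumes", call. = FALSE)
  out <- ts[-seq_len(n_discard), , drop = FALSE]
  attr(out, "tr_seconds") <- attr(ts, "tr_seconds")
  out
}
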