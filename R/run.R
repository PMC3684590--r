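#' Pipeline run configuration
#'
#' Single configuration object for an end-to-end synthetic run: cohort sizes
#' (original and replication), connectome dimension, selection parameters,
#' overlap thresholds and the master seed. Defaults are desk-scale: 90
#' regions (4005 edges), 20+20 original and 9+8 replication subjects, 200
#' permutations.
#'
#' @param seed master seed; every random draw in the run derives from it.
#' @param n_rois regions in the parcellation.
#' @param n_patients,n_controls original-cohort group sizes.
#' @param n_rep_patients,n_rep_controls replication-cohort group sizes.
#' @param p_level,corr_alpha,n_permutations selection parameters.
#' @param tau_list overlap thresholds.
#' @param tau_report threshold used for the severity and network stages.
#' @param band band-pass edges in Hz (metadata for the manifest; the default
#'   run simulates at the edge level).
#' @param tr_seconds repetition time.
#' @param effects a [planted_effects()] object, or `NULL` for
#'   [default_effects()] drawn from the seed.
#' @param feature_mode LOOCV feature mode.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_rois = 90, n_patients = 20,
                            n_controls = 20, n_rep_patients = 9,
                            n_rep_controls = 8, p_level = 0.01,
                            corr_alpha = 0.05, n_permutations = 200,
                            tau_list = c(1, 0.95, 0.9, 0.85),
                            tau_report = 0.9, band = c(0.01, 0.08),
                            tr_seconds = 2, effects = NULL,
                            feature_mode = "per_fold") {
  if (any(tau_list <= 0 | tau_list > 1)) stop("tau_list must be in (0,1]", call. = FALSE)
  cfg <- list(seed = as.integer(seed), n_rois = n_rois,
              n_patients = n_patients, n_controls = n_controls,
              n_rep_patients = n_rep_patients, n_rep_controls = n_rep_controls,
              p_level = p_level, corr_alpha = corr_alpha,
              n_permutations = n_permutations, tau_list = tau_list,
              tau_report = tau_report, band = band, tr_seconds = tr_seconds,
              effects = effects, feature_mode = feature_mode)
  class(cfg) <- "pipeline_config"
  cfg
}

# deterministic CSV writer: numerics rounded to 10 significant digits
.write_table <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], 10)
  }
  write.csv(df, path, row.names = FALSE, quote = TRUE, eol = "\n")
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
}

.stable_edge_table <- function(stab, n_rois) {
  if (!nrow(stab)) {
    return(data.frame(index = integer(0), roi_i = integer(0),
                      roi_j = integer(0), recurrence = numeric(0)))
  }
  prs <- edge_pair(stab$index, n_rois)
  data.frame(index = stab$index, roi_i = prs[, 1], roi_j = prs[, 2],
             recurrence = stab$recurrence)
}

.report_list <- function(rep) {
  rep[c("sensitivity", "specificity", "accuracy", "correct_patients",
        "total_patients", "correct_controls", "total_controls", "auc",
        "perm_p")]
}

#' Run the full pipeline on a seeded synthetic cohort
#'
#' Simulates the study conditions (original + replication cohorts, atlas,
#' planted abnormal edges), fits the discrimination model, evaluates the
#' replication cohort at every overlap threshold, runs the severity stage
#' (LOO-SVR predictions, relative errors, CSI and its correlations) and the
#' network report, and writes every artifact plus a manifest into `out_dir`.
#' Re-running with an identical configuration reproduces identical files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with the in-memory results: `fit`, `cohort`,
#'   `replication`, `atlas`, `effects`, `rep_reports`, `csi`, `csi_cor`,
#'   `score_errors`, `network`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  eff <- config$effects
  if (is.null(eff)) {
    eff <- default_effects(config$n_rois, seed = fold_seed(config$seed, 11))
  }
  cohort <- simulate_cohort(config$n_patients, config$n_controls,
                            seed = fold_seed(config$seed, 12))
  replication <- simulate_cohort(config$n_rep_patients, config$n_rep_controls,
                                 seed = fold_seed(config$seed, 13))
  replication$subject_id <- paste0("REP_", replication$subject_id)
  atlas <- simulate_atlas(config$n_rois, seed = fold_seed(config$seed, 14))
  X <- simulate_edge_data(cohort, config$n_rois, eff,
                          seed = fold_seed(config$seed, 15))
  Xrep <- simulate_edge_data(replication, config$n_rois, eff,
                             seed = fold_seed(config$seed, 16))

  params <- selection_params(config$p_level, config$n_permutations,
                             config$corr_alpha, seed = config$seed)
  fit <- fd_mvpa(X, cohort$group, cohort$ndi_qol, params,
                 tau_list = config$tau_list,
                 feature_mode = config$feature_mode)

  rep_reports <- lapply(seq_along(config$tau_list), function(m) {
    stab <- fit$stable[[m]]
    if (!nrow(stab)) return(NULL)
    r <- replicate_classify(X, cohort$group, stab, Xrep, replication$group)
    c(list(tau = config$tau_list[m], n_features = nrow(stab)),
      .report_list(r))
  })
  names(rep_reports) <- names(fit$stable)

  stab_report <- stabilize(fit$subsets, config$tau_report)
  severity <- NULL
  network <- NULL
  if (nrow(stab_report)) {
    csi <- csi_table(cohort, X, stab_report)
    csi_cor <- csi_correlations(csi)
    pat <- cohort$group == "patient"
    score_errors <- lapply(c("ndi_symptom", "sds", "sas", "duration_months"),
                           function(v) {
      pred <- predict_scores(X[pat, , drop = FALSE], cohort[[v]][pat],
                             stab_report)
      err <- relative_error(pred, cohort[[v]][pat])
      list(variable = v, mean_relative_error = mean(err, na.rm = TRUE))
    })
    severity <- list(csi = csi, csi_cor = csi_cor, score_errors = score_errors)
    ann <- annotate_edges(stab_report, atlas, X, cohort$ndi_qol,
                          cohort$age_years)
    network <- list(
      annotations = ann,
      node_weights = node_weights(stab_report, config$n_rois),
      length_test = suppressWarnings(sign_split_length_test(ann)),
      system_proportions = system_proportions(ann, atlas)
    )
  }

  # ---- artifacts ----
  .write_table(cohort, file.path(out_dir, "subjects.csv"))
  .write_table(replication, file.path(out_dir, "replication_subjects.csv"))
  .write_table(atlas, file.path(out_dir, "atlas.csv"))
  .write_table(data.frame(subject_id = rownames(X), X, check.names = FALSE),
               file.path(out_dir, "features.csv"))
  prs <- edge_pairs(config$n_rois)
  .write_json(list(n_rois = config$n_rois, n_edges = n_edges(config$n_rois),
                   order = "row-major strict upper triangle",
                   first_pairs = lapply(seq_len(min(5, nrow(prs))),
                                        function(k) as.integer(prs[k, ]))),
              file.path(out_dir, "features_index.json"))
  .write_table(data.frame(
    fold = rep(seq_along(fit$subsets$subsets), lengths(fit$subsets$subsets)),
    index = unlist(fit$subsets$subsets)),
    file.path(out_dir, "fold_subsets.csv"))
  for (m in seq_along(config$tau_list)) {
    .write_table(.stable_edge_table(fit$stable[[m]], config$n_rois),
                 file.path(out_dir, sprintf("stable_tau_%03d.csv",
                                            round(100 * config$tau_list[m]))))
  }
  .write_json(.report_list(fit$report), file.path(out_dir, "classification.json"))
  .write_json(rep_reports, file.path(out_dir, "replication.json"))
  if (!is.null(severity)) {
    .write_table(severity$csi, file.path(out_dir, "csi.csv"))
    .write_json(list(correlations = severity$csi_cor,
                     score_errors = severity$score_errors),
                file.path(out_dir, "csi_correlations.json"))
  }
  if (!is.null(network)) {
    .write_table(network$annotations, file.path(out_dir, "network_edges.csv"))
    .write_table(data.frame(roi_id = seq_len(config$n_rois),
                            weight = as.integer(network$node_weights)),
                 file.path(out_dir, "network_nodes.csv"))
    .write_json(list(length_test = network$length_test,
                     system_proportions = network$system_proportions),
                file.path(out_dir, "network_report.json"))
  }
  manifest <- list(
    package = "dysconnect",
    version = as.character(utils::packageVersion("dysconnect")),
    seed = config$seed,
    config = config[setdiff(names(config), "effects")],
    planted = list(indices = eff$feature_indices,
                   group_shift = eff$group_shift,
                   qol_slope = eff$qol_slope, noise_sd = eff$noise_sd)
  )
  .write_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(fit = fit, cohort = cohort, replication = replication,
                 atlas = atlas, effects = eff, rep_reports = rep_reports,
                 csi = severity$csi, csi_cor = severity$csi_cor,
                 score_errors = severity$score_errors, network = network))
}

#' Write / read the standard cohort tables
#'
#' Plain-CSV persistence for subject tables, atlases and feature matrices
#' (features get a JSON sidecar describing the edge-index convention).
#'
#' @param cohort,atlas,features objects to write.
#' @param path file path.
#' @name dysconnect-io
#' @export
write_subject_table <- function(cohort, path) .write_table(cohort, path)

#' @rdname dysconnect-io
#' @export
read_subject_table <- function(path) {
  out <- read.csv(path)
  out$group <- factor(out$group, levels = c("control", "patient"))
  out
}

#' @rdname dysconnect-io
#' @export
write_atlas <- function(atlas, path) .write_table(atlas, path)

#' @rdname dysconnect-io
#' @export
read_atlas <- function(path) read.csv(path)

#' @rdname dysconnect-io
#' @param n_rois connectome dimension recorded in the sidecar.
#' @export
write_features <- function(features, path, n_rois = attr(features, "n_rois")) {
  .write_table(data.frame(subject_id = rownames(features), features,
                          check.names = FALSE), path)
  .write_json(list(n_rois = n_rois, n_edges = ncol(features),
                   order = "row-major strict upper triangle"),
              paste0(path, ".json"))
}

#' @rdname dysconnect-io
#' @export
read_features <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df[[1]]
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    attr(X, "n_rois") <- jsonlite::read_json(side)$n_rois
  }
  X
}
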