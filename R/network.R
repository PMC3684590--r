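#' Node occurrence weights of the abnormal network
#'
#' Counts, for every ROI, the stable abnormal edges incident to it. The
#' weights satisfy the handshake identity (they sum to twice the edge count);
#' the argmax is reported as the dominant region.
#'
#' @param stable a [stabilize()] result or integer vector of edge indices.
#' @param n_rois number of regions.
#' @return integer vector of length `n_rois` with attribute `dominant` (the
#'   ROI of maximal weight).
#' @export
node_weights <- function(stable, n_rois) {
  idx <- if (inherits(stable, "stable_features")) stable$index else
    as.integer(stable)
  if (!length(idx)) stop("stable feature set is empty", call. = FALSE)
  prs <- edge_pair(idx, n_rois)
  w <- tabulate(c(prs), nbins = n_rois)
  names(w) <- seq_len(n_rois)
  attr(w, "dominant") <- as.integer(which.max(w))
  w
}

#' Euclidean connection lengths
#'
#' 3-D Euclidean distance in millimetres between the centroids of the two
#' ROIs of each edge.
#'
#' @param stable stable feature set or integer edge indices.
#' @param atlas atlas data.frame with `roi_id`, `x_mm`, `y_mm`, `z_mm`.
#' @return numeric vector of lengths (mm), one per edge.
#' @export
connection_lengths <- function(stable, atlas) {
  idx <- if (inherits(stable, "stable_features")) stable$index else
    as.integer(stable)
  prs <- edge_pair(idx, nrow(atlas))
  pos <- match(c(prs), atlas$roi_id)
  if (anyNA(pos)) {
    stop(sprintf("missing centroid for ROI(s): %s",
                 paste(unique(c(prs)[is.na(pos)]), collapse = ", ")),
         call. = FALSE)
  }
  xyz <- as.matrix(atlas[, c("x_mm", "y_mm", "z_mm")])
  a <- xyz[match(prs[, 1], atlas$roi_id), , drop = FALSE]
  b <- xyz[match(prs[, 2], atlas$roi_id), , drop = FALSE]
  sqrt(rowSums((a - b)^2))
}

#' Annotate the stable abnormal edges
#'
#' Builds the per-edge annotation table driving the network report: ROI pair,
#' Euclidean length, partial correlation with NDI-QoL controlling for age
#' (sign classifies the edge; an exact zero is classified positive), and the
#' cortical-system labels of the two endpoints.
#'
#' @param stable stable feature set.
#' @param atlas atlas data.frame with centroids and `system` labels.
#' @param features subjects x edges matrix.
#' @param qol,age per-subject vectors (all subjects).
#' @return data.frame of class `edge_annotations`.
#' @export
annotate_edges <- function(stable, atlas, features, qol, age) {
  idx <- if (inherits(stable, "stable_features")) stable$index else
    as.integer(stable)
  if (!length(idx)) stop("stable feature set is empty", call. = FALSE)
  if (any(is.na(atlas$system) | !nzchar(atlas$system)))
    stop("unlabeled ROI in atlas", call. = FALSE)
  prs <- edge_pair(idx, nrow(atlas))
  pc <- edge_qol_partial_corr(features, qol, age, idx)
  out <- data.frame(
    index = idx,
    roi_i = prs[, 1], roi_j = prs[, 2],
    length_mm = connection_lengths(idx, atlas),
    qol_r = pc$r, qol_p = pc$p,
    qol_sign = ifelse(pc$r < 0, "negative", "positive"),
    system_i = atlas$system[match(prs[, 1], atlas$roi_id)],
    system_j = atlas$system[match(prs[, 2], atlas$roi_id)]
  )
  structure(out, class = c("edge_annotations", "data.frame"))
}

#' Length comparison between negatively and positively correlated connections
#'
#' Mean and SD of the Euclidean connection length per QoL-correlation sign
#' group, plus a two-sided pooled-variance two-sample t-test of the lengths.
#' If either sign group has fewer than 2 edges the test is skipped with a
#' warning.
#'
#' @param annotations an [annotate_edges()] table.
#' @return list with per-group `n`, `mean`, `sd`, and `t`, `df`, `p` (NA if
#'   skipped).
#' @export
sign_split_length_test <- function(annotations) {
  neg <- annotations$length_mm[annotations$qol_sign == "negative"]
  pos <- annotations$length_mm[annotations$qol_sign == "positive"]
  out <- list(n_negative = length(neg), mean_negative = mean(neg),
              sd_negative = sd(neg),
              n_positive = length(pos), mean_positive = mean(pos),
              sd_positive = sd(pos),
              t = NA_real_, df = NA_real_, p = NA_real_)
  if (length(neg) < 2 || length(pos) < 2) {
    warning("a sign group has fewer than 2 edges; length test skipped")
    return(out)
  }
  tt <- t.test(neg, pos, var.equal = TRUE)
  out$t <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out$p <- tt$p.value
  out
}

#' Sign proportions per cortical system
#'
#' Tallies, for each cortical system, the abnormal edges touching it (an edge
#' between two systems counts once in each; an edge within one system counts
#' once for it) split by the sign of their QoL correlation, and the resulting
#' fraction of negative edges.
#'
#' @param annotations an [annotate_edges()] table.
#' @param atlas atlas data.frame (fixes the set of systems reported).
#' @return data.frame `system`, `n_negative`, `n_positive`,
#'   `fraction_negative`.
#' @export
system_proportions <- function(annotations, atlas) {
  systems <- sort(unique(atlas$system))
  rows <- lapply(systems, function(s) {
    touch <- annotations$system_i == s | annotations$system_j == s
    n_neg <- sum(touch & annotations$qol_sign == "negative")
    n_pos <- sum(touch & annotations$qol_sign == "positive")
    data.frame(system = s, n_negative = n_neg, n_positive = n_pos,
               fraction_negative = if (n_neg + n_pos > 0)
                 n_neg / (n_neg + n_pos) else NA_real_)
  })
  do.call(rbind, rows)
}
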