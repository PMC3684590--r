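#' Feature-selection parameters
#'
#' Bundles the tuning knobs of the fold-wise edge selection: the significance
#' level `p_level` of the permutation-calibrated group t-test (explored over
#' 0.05 down to 0.00001), the number of label permutations forming the
#' empirical null per fold, the level `corr_alpha` of the NDI-QoL correlation
#' filter, and the master RNG seed from which per-fold permutation seeds are
#' derived deterministically.
#'
#' @param p_level significance level of the permutation filter, in (0, 1).
#' @param n_permutations label permutations per fold (>= 100; 1000 in the
#'   reference analysis).
#' @param corr_alpha two-sided significance level of the QoL-correlation
#'   filter.
#' @param seed integer master seed.
#' @return an object of class `selection_params`.
#' @export
selection_params <- function(p_level = 0.01, n_permutations = 1000,
                             corr_alpha = 0.05, seed = 1L) {
  if (!(is.numeric(p_level) && length(p_level) == 1 && p_level > 0 && p_level < 1))
    stop("p_level must be in (0, 1)", call. = FALSE)
  stopifnot_scalar_count(n_permutations, "n_permutations", min = 100)
  if (!(is.numeric(corr_alpha) && length(corr_alpha) == 1 &&
        corr_alpha > 0 && corr_alpha <= 1))
    stop("corr_alpha must be in (0, 1]", call. = FALSE)
  structure(list(p_level = p_level,
                 n_permutations = as.integer(n_permutations),
                 corr_alpha = corr_alpha, seed = as.integer(seed)),
            class = "selection_params")
}

#' Per-edge two-sample t-test between groups
#'
#' Pooled-variance two-sided two-sample t-test of every edge (column) between
#' the healthy and patient matrices. Edges with zero pooled variance have an
#' undefined statistic and are returned as `NA` (they are treated as
#' non-significant by the filters).
#'
#' @param healthy `n1 x E` matrix of edge features for controls.
#' @param patient `n2 x E` matrix for patients; `n1, n2 >= 2`.
#' @return list with numeric vectors `t`, `p` (two-sided), scalar `df`, and
#'   logical `degenerate` flagging zero-pooled-variance edges.
#' @export
group_ttest <- function(healthy, patient) {
  healthy <- as.matrix(healthy); patient <- as.matrix(patient)
  n1 <- nrow(healthy); n2 <- nrow(patient)
  if (n1 < 2 || n2 < 2) stop("need at least 2 subjects per group", call. = FALSE)
  if (ncol(healthy) != ncol(patient)) stop("edge dimension mismatch", call. = FALSE)
  m1 <- colMeans(healthy); m2 <- colMeans(patient)
  ss <- colSums(healthy^2) - n1 * m1^2 + colSums(patient^2) - n2 * m2^2
  df <- n1 + n2 - 2
  sp2 <- ss / df
  denom <- sqrt(pmax(sp2, 0) * (1 / n1 + 1 / n2))
  degenerate <- !(denom > sqrt(.Machine$double.eps) * (abs(m1) + abs(m2) + 1))
  t <- (m2 - m1) / denom
  t[degenerate & abs(m2 - m1) < 1e-12] <- NA_real_
  p <- 2 * pt(-abs(t), df)
  p[is.na(t)] <- NA_real_
  list(t = t, p = p, df = df, degenerate = degenerate & is.na(t))
}

# One permuted 0/1 patient-assignment row per permutation: n1 of the
# `included` subjects become patients; all other entries stay 0.
.draw_perm_rows <- function(n, included, n1, n_perm) {
  P <- matrix(0, n_perm, n)
  for (b in seq_len(n_perm)) P[b, sample(included, n1)] <- 1
  P
}

# Deterministic permutation-seed key for a set of excluded subjects: single
# folds use their own index, pair exclusions a distinct pair code.
.exclude_key <- function(exclude, n) {
  if (length(exclude) <= 1) {
    if (length(exclude)) exclude else 0L
  } else {
    (min(exclude) - 1) * n + max(exclude) + n
  }
}

# Batched fold statistics: for each exclusion set, the permutation p-value of
# the group t-test and the QoL-correlation p-value at every edge, computed on
# the remaining subjects. One joint label shuffle per permutation across all
# edges; per-fold shuffles are seeded from (params$seed, exclusion key).
.fold_statistics <- function(features, labels, qol, params,
                             excludes = as.list(seq_len(nrow(features)))) {
  X <- as.matrix(features)
  n <- nrow(X)
  labels <- factor(labels, levels = c("control", "patient"))
  pat <- as.numeric(labels == "patient")
  F_ <- length(excludes)
  B <- params$n_permutations

  include <- matrix(1, F_, n)
  for (f in seq_len(F_)) include[f, excludes[[f]]] <- 0
  pat_inc <- sweep(include, 2, pat, "*")
  n1 <- rowSums(pat_inc)
  n2 <- rowSums(include) - n1
  if (any(n1 < 2) || any(n2 < 2)) stop("a fold lost an entire group", call. = FALSE)

  P <- matrix(0, F_ * B, n)
  for (f in seq_len(F_)) {
    incl <- which(include[f, ] == 1)
    rows <- with_seed(fold_seed(params$seed, .exclude_key(excludes[[f]], n)),
                      .draw_perm_rows(n, incl, n1[f], B))
    P[(f - 1) * B + seq_len(B), ] <- rows
  }
  fold_of_row <- rep(seq_len(F_), each = B)
  # block size balancing cache locality against the (F*B) x block intermediate
  block <- max(128L, min(500L, as.integer(8e6 / (F_ * B))))
  res <- .perm_ttest_counts(X, pat, include, P, fold_of_row, block)
  p_perm <- (1 + res$count) / (B + 1)
  ok <- !is.nan(res$tobs2)

  # QoL-correlation p per fold, vectorized over folds via matrix products
  X2 <- X * X
  q <- as.numeric(qol)
  W <- pat_inc
  m <- n1
  Sx <- W %*% X
  Sxx <- W %*% X2
  Sqx <- (W * matrix(q, F_, n, byrow = TRUE)) %*% X
  sq <- as.numeric(W %*% q)
  sqq <- as.numeric(W %*% (q * q))
  cov_xy <- Sqx - Sx * (sq / m)
  varx <- pmax(Sxx - Sx^2 / m, 0)
  varq <- pmax(sqq - sq^2 / m, 0)
  if (any(varq <= 0)) stop("qol has zero variance within a fold", call. = FALSE)
  denom <- sqrt(varx * varq)
  r <- cov_xy / denom
  r[denom == 0] <- NA_real_
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((m - 2) / pmax(1 - r^2, .Machine$double.eps))
  p_qol <- matrix(2 * pt(-abs(tstat), m - 2), F_, ncol(X))

  list(p_perm = p_perm, ok = ok, p_qol = p_qol, tobs2 = res$tobs2,
       n_edges = ncol(X))
}

# Retained-edge indices for one exclusion row of .fold_statistics output.
.mask_from_stats <- function(stats, f, p_level, corr_alpha) {
  which(stats$ok[f, ] & stats$p_perm[f, ] <= p_level &
          !is.na(stats$p_qol[f, ]) & stats$p_qol[f, ] <= corr_alpha)
}

#' Permutation-calibrated group-difference filter
#'
#' For every edge, compares the observed two-sample t-test against an
#' empirical null built by randomly permuting the group labels
#' `n_permutations` times (one joint label shuffle per iteration across all
#' edges, preserving cross-edge dependence and the group sizes) and
#' recomputing the test. An edge is retained iff the rank of its observed
#' p-value within the permutation null satisfies
#' `rank / (n_permutations + 1) <= p_level` — equivalently, iff its
#' permutation p-value on |t| is at most `p_level`. Degenerate
#' (zero-variance) edges are never retained. Note the resolution floor: no
#' edge can be retained when `p_level < 1 / (n_permutations + 1)`.
#'
#' @inheritParams group_ttest
#' @param p_level significance level.
#' @param n_permutations number of label permutations.
#' @param seed RNG seed for the shuffles.
#' @return logical mask over edges with attributes `p_observed` (parametric
#'   two-sided p) and `p_perm` (permutation p-value `(1 + #null >= obs) /
#'   (n_permutations + 1)`).
#' @export
permutation_filter <- function(healthy, patient, p_level = 0.01,
                               n_permutations = 1000, seed = NULL) {
  healthy <- as.matrix(healthy); patient <- as.matrix(patient)
  if (nrow(healthy) < 2 || nrow(patient) < 2)
    stop("need at least 2 subjects per group", call. = FALSE)
  X <- rbind(healthy, patient)
  n <- nrow(X)
  pat <- c(rep(0, nrow(healthy)), rep(1, nrow(patient)))
  P <- with_seed(seed, .draw_perm_rows(n, seq_len(n), nrow(patient),
                                       n_permutations))
  res <- .perm_ttest_counts(X, pat, matrix(1, 1, n), P,
                            rep(1L, n_permutations), 500L)
  tobs2 <- as.vector(res$tobs2)
  p_perm <- (1 + as.vector(res$count)) / (n_permutations + 1)
  mask <- !is.nan(tobs2) & p_perm <= p_level
  p_obs <- 2 * pt(-sqrt(tobs2), n - 2)
  p_obs[is.infinite(tobs2)] <- 0
  attr(mask, "p_observed") <- p_obs
  attr(mask, "p_perm") <- p_perm
  mask
}

#' NDI-QoL correlation filter
#'
#' Pearson-correlates every edge with the patients' NDI-QoL scores and retains
#' edges whose two-sided correlation p-value is at most `corr_alpha`.
#'
#' @param patient `n2 x E` patient feature matrix, `n2 >= 4`.
#' @param qol length-`n2` NDI-QoL vector (must have nonzero variance).
#' @param corr_alpha significance level; `corr_alpha = 1` retains everything.
#' @return logical mask with attributes `r` and `p`.
#' @export
qol_correlation_filter <- function(patient, qol, corr_alpha = 0.05) {
  patient <- as.matrix(patient)
  n <- nrow(patient)
  if (n < 4) stop("need at least 4 patients", call. = FALSE)
  if (length(qol) != n) stop("qol length mismatch", call. = FALSE)
  if (sd(qol) == 0) stop("qol has zero variance", call. = FALSE)
  r <- suppressWarnings(as.vector(cor(qol, patient)))
  r[!is.finite(r)] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), n - 2)
  mask <- !is.na(p) & p <= corr_alpha
  attr(mask, "r") <- r
  attr(mask, "p") <- p
  mask
}

# Selection mask (edge indices) on the cohort minus the subjects in `exclude`.
.selection_mask <- function(features, labels, qol, params, exclude) {
  stats <- .fold_statistics(features, labels, qol, params,
                            excludes = list(exclude))
  .mask_from_stats(stats, 1, params$p_level, params$corr_alpha)
}

#' Fold-wise feature subsets under leave-one-out cross-validation
#'
#' For each subject in turn, runs the complete edge selection (permutation
#' filter intersected with the QoL-correlation filter) on all remaining
#' subjects, so the held-out subject never influences its own fold's feature
#' subset. Per-fold permutation seeds derive deterministically from
#' `params$seed` and the fold id, making each fold independently
#' reproducible.
#'
#' @param features subjects x edges matrix.
#' @param labels factor with levels control/patient, one per row.
#' @param qol numeric NDI-QoL per subject (the filter uses the training
#'   patients' entries).
#' @param params a [selection_params()].
#' @return object of class `fold_subsets`: list with `subsets` (one integer
#'   vector of retained edge indices per fold), `n_folds`, `n_edges`,
#'   `params`.
#' @export
fold_subsets <- function(features, labels, qol, params = selection_params()) {
  features <- as.matrix(features)
  n <- nrow(features)
  labels <- factor(labels, levels = c("control", "patient"))
  if (length(labels) != n || length(qol) != n)
    stop("labels/qol must match rows of features", call. = FALSE)
  if (min(table(labels)) < 3)
    stop("need at least 3 subjects per group", call. = FALSE)
  stats <- .fold_statistics(features, labels, qol, params)
  subsets <- lapply(seq_len(n), function(k) {
    .mask_from_stats(stats, k, params$p_level, params$corr_alpha)
  })
  structure(list(subsets = subsets, n_folds = n, n_edges = ncol(features),
                 params = params),
            class = "fold_subsets")
}

#' @export
print.fold_subsets <- function(x, ...) {
  sizes <- lengths(x$subsets)
  cat(sprintf("Fold-wise feature subsets: %d folds over %d edges\n",
              x$n_folds, x$n_edges))
  cat(sprintf("  retained per fold: min %d / median %g / max %d\n",
              min(sizes), median(sizes), max(sizes)))
  invisible(x)
}

#' Stabilize fold subsets with an overlap threshold
#'
#' Counts, for every edge, the number of LOOCV folds `M` (out of `N`) whose
#' subset contains it; the recurrence rate is `M/N`. Edges with recurrence at
#' least `tau` form the stable feature subset. `tau = 1` is the consensus
#' (intersection) set; lowering `tau` (e.g. 100%, 95%, 90%, 85%) weakly grows
#' the set.
#'
#' @param subsets a [fold_subsets()] object, or a plain list of integer index
#'   vectors.
#' @param tau overlap threshold in (0, 1].
#' @return object of class `stable_features`: data.frame with columns `index`
#'   and `recurrence`, attributes `tau`, `n_folds` and `rates` (recurrence of
#'   every ever-selected edge).
#' @export
stabilize <- function(subsets, tau = 0.9) {
  if (inherits(subsets, "fold_subsets")) subsets <- subsets$subsets
  if (!length(subsets)) stop("no fold subsets", call. = FALSE)
  if (!(tau > 0 && tau <= 1)) stop("tau must be in (0, 1]", call. = FALSE)
  N <- length(subsets)
  counts <- table(unlist(subsets))
  idx <- as.integer(names(counts))
  rate <- as.integer(counts) / N
  keep <- rate >= tau - 1e-9
  out <- data.frame(index = idx[keep], recurrence = rate[keep])
  out <- out[order(out$index), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("stable_features", "data.frame"),
            tau = tau, n_folds = N,
            rates = stats::setNames(rate, idx))
}

#' @export
print.stable_features <- function(x, ...) {
  cat(sprintf("Stable feature set: %d edges at overlap threshold %.2f (%d folds)\n",
              nrow(x), attr(x, "tau"), attr(x, "n_folds")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more\n", nrow(x) - 10))
  invisible(x)
}
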