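# Synthetic cohort generator.
#
# Emulates the data-generating story the estimators assume: each subject's
# clean signal is drawn i.i.d. over time from a zero-mean Gaussian with a
# sparse ROI-level precision matrix (so SR's partial-correlation target has a
# known support), and is contaminated by additive noise whose T x T temporal
# covariance is shared across ROIs - an AR(1) covariance by default, the
# simplest structure whose precision is sparse (tridiagonal), matching the
# rationale of the L1 noise prior. Group differences for classification tests
# are injected on the precision (partial-correlation) scale.

#' Synthetic cohort configuration
#'
#' Defaults mirror the resting-state shape the package targets (170 time
#' points, 90 cerebrum ROIs, 45 subjects per group) with moderate AR(1)
#' temporal noise.
#'
#' @param n_roi number of ROIs (N).
#' @param n_time number of time points (T).
#' @param n_per_group subjects per class.
#' @param edge_density expected fraction of ROI pairs with a true edge,
#'   in (0, 1).
#' @param ar_rho AR(1) lag-1 correlation of the temporal noise, in (-1, 1);
#'   0 gives i.i.d. noise.
#' @param noise_scale noise standard-deviation multiplier `sigma` (0 = clean).
#' @param effect_size additive group effect applied to `n_effect_edges`
#'   randomly chosen entries of the patient group's precision matrix.
#' @param n_effect_edges number of ROI pairs carrying the group effect.
#' @param seed integer seed making the whole cohort deterministic.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_roi = 90L, n_time = 170L, n_per_group = 45L,
                         edge_density = 0.1, ar_rho = 0.6, noise_scale = 0.5,
                         effect_size = 1, n_effect_edges = 20L, seed = 1L) {
  if (edge_density <= 0 || edge_density >= 1)
    stop("edge_density must be in (0, 1)")
  if (abs(ar_rho) >= 1) stop("ar_rho must be in (-1, 1)")
  if (noise_scale < 0) stop("noise_scale must be nonnegative")
  if (n_roi < 2 || n_time < 3) stop("need n_roi >= 2 and n_time >= 3")
  structure(list(n_roi = as.integer(n_roi), n_time = as.integer(n_time),
                 n_per_group = as.integer(n_per_group),
                 edge_density = edge_density, ar_rho = ar_rho,
                 noise_scale = noise_scale, effect_size = effect_size,
                 n_effect_edges = as.integer(n_effect_edges),
                 seed = as.integer(seed)),
            class = "synth_config")
}

ar1_covariance <- function(n_time, rho) {
  idx <- seq_len(n_time)
  rho^abs(outer(idx, idx, "-"))
}

#' Ground truth for a synthetic cohort
#'
#' Samples a sparse ROI precision matrix (support drawn at `edge_density`,
#' signed off-diagonal magnitudes in [0.3, 0.6], diagonal set to the absolute
#' row sum plus 1 so the matrix is strictly diagonally dominant, hence PD),
#' the AR(1) temporal noise covariance, and the patient-group effect (added
#' to `n_effect_edges` randomly chosen precision entries, with a
#' diagonal-boost repair if positive definiteness is lost). Deterministic
#' given `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return An object of class `fbn_ground_truth` with `roi_precision`,
#'   `roi_precision_patient`, `support` (2-column matrix of true edges,
#'   i < j), `temporal_noise_cov`, `noise_scale`, `group_effect`, `config`.
#' @export
make_ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_roi
  idx <- feature_index(n)
  on_edge <- rbinom(nrow(idx), 1L, cfg$edge_density) == 1L
  vals <- numeric(nrow(idx))
  vals[on_edge] <- runif(sum(on_edge), 0.3, 0.6) *
    sample(c(-1, 1), sum(on_edge), replace = TRUE)
  prec <- features_to_matrix(vals, n)
  diag(prec) <- rowSums(abs(prec)) + 1
  # patient group: shift a random subset of precision entries
  eff_rows <- sample.int(nrow(idx), min(cfg$n_effect_edges, nrow(idx)))
  prec_pat <- prec
  for (r in eff_rows) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    prec_pat[i, j] <- prec_pat[i, j] + cfg$effect_size
    prec_pat[j, i] <- prec_pat[i, j]
  }
  ev <- min(eigen(prec_pat, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 0.05) {
    warning("patient-group precision lost positive definiteness; ",
            "boosting its diagonal by ", format(0.05 - ev, digits = 3))
    prec_pat <- prec_pat + diag(0.05 - ev, n)
  }
  structure(
    list(roi_precision = prec, roi_precision_patient = prec_pat,
         support = idx[on_edge, , drop = FALSE],
         temporal_noise_cov = ar1_covariance(cfg$n_time, cfg$ar_rho),
         noise_scale = cfg$noise_scale,
         group_effect = list(edges = idx[eff_rows, , drop = FALSE],
                             effect_size = cfg$effect_size),
         config = cfg),
    class = "fbn_ground_truth")
}

#' Simulate one subject's ROI time series
#'
#' Clean rows are i.i.d. draws from the zero-mean Gaussian with the group's
#' ROI precision; the additive noise is `sigma * L %*% Z` with `L` the
#' Cholesky factor of the temporal noise covariance and `Z` standard normal,
#' so every ROI's noise column shares the same temporal covariance. Uses the
#' current RNG state (seed via `set.seed()` or use [simulate_cohort()]).
#' The result is raw (not normalized).
#'
#' @param gt an `fbn_ground_truth`.
#' @param group 1 = patient (uses the effect-shifted precision), 0 = control.
#' @param subject_id identifier stored in the result.
#' @return An [fbn_ts].
#' @export
simulate_subject <- function(gt, group = 0L, subject_id = "") {
  stopifnot(inherits(gt, "fbn_ground_truth"))
  cfg <- gt$config
  prec <- if (group == 1L) gt$roi_precision_patient else gt$roi_precision
  sigma_roi <- chol2inv(chol(prec))            # Sigma = P^{-1}
  a <- chol((sigma_roi + t(sigma_roi)) / 2)    # Sigma = A'A
  z <- matrix(rnorm(cfg$n_time * cfg$n_roi), cfg$n_time, cfg$n_roi)
  clean <- z %*% a
  x <- clean
  if (gt$noise_scale > 0) {
    l <- t(chol(gt$temporal_noise_cov))
    z2 <- matrix(rnorm(cfg$n_time * cfg$n_roi), cfg$n_time, cfg$n_roi)
    x <- clean + gt$noise_scale * (l %*% z2)
  }
  colnames(x) <- sprintf("ROI%d", seq_len(cfg$n_roi))
  fbn_ts(x, subject_id = subject_id)
}

#' Simulate a two-group cohort
#'
#' `n_per_group` patients followed by `n_per_group` controls (labels
#' `1, ..., 1, 0, ..., 0`), deterministic given `cfg$seed`: the ground truth
#' consumes `seed` and the subject draws consume `seed + 1`.
#'
#' @param cfg a [synth_config()].
#' @return List with `ts` (list of [fbn_ts]), `labels`, `subject_ids`,
#'   `ground_truth`.
#' @export
simulate_cohort <- function(cfg) {
  gt <- make_ground_truth(cfg)
  set.seed(cfg$seed + 1L)
  n_tot <- 2L * cfg$n_per_group
  labels <- rep(c(1L, 0L), each = cfg$n_per_group)
  ids <- sprintf("sub-%03d", seq_len(n_tot))
  ts <- lapply(seq_len(n_tot), function(k)
    simulate_subject(gt, group = labels[k], subject_id = ids[k]))
  list(ts = ts, labels = labels, subject_ids = ids, ground_truth = gt)
}

#' Edge-support recovery score
#'
#' Takes the `top_k` largest-magnitude off-diagonal entries of the
#' symmetrized weight matrix as predicted edges and scores them against the
#' true support: precision, recall and F1.
#'
#' @param net an `fbn` fit or weight matrix.
#' @param gt an `fbn_ground_truth`.
#' @param top_k number of predicted edges (default: true support size).
#' @return Named list `precision`, `recall`, `f1`.
#' @export
recovery_score <- function(net, gt, top_k = nrow(gt$support)) {
  feats <- extract_upper_features(net)
  if (top_k > length(feats)) stop("top_k exceeds the number of ROI pairs")
  idx <- feature_index(length(feats_to_n(feats)))
  ord <- order(abs(feats), decreasing = TRUE)
  predicted <- ord[seq_len(top_k)]
  true_set <- match(paste(gt$support[, 1L], gt$support[, 2L]),
                    paste(idx[, 1L], idx[, 2L]))
  tp <- length(intersect(predicted, true_set))
  prec <- if (top_k > 0) tp / top_k else 0
  rec <- if (length(true_set) > 0) tp / length(true_set) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1)
}

# invert p = n(n-1)/2
feats_to_n <- function(feats) {
  p <- length(feats)
  n <- (1 + sqrt(1 + 8 * p)) / 2
  if (abs(n - round(n)) > 1e-8)
    stop("feature vector length is not n*(n-1)/2 for integer n")
  seq_len(round(n))
}
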