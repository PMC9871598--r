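# Edge features and classification metrics.

#' Upper-triangle index map
#'
#' Row-major upper-triangle ordering used for all edge feature vectors:
#' (1,2), (1,3), ..., (1,N), (2,3), ..., (N-1,N).
#'
#' @param n number of ROIs.
#' @return Integer matrix with `n*(n-1)/2` rows and columns `i`, `j`
#'   (1-based, `i < j`).
#' @export
feature_index <- function(n) {
  if (n < 2) stop("need at least 2 ROIs")
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(i = i, j = as.integer(j))
}

#' Extract upper-triangle edge features from a network
#'
#' Since a (symmetrized) FBN is symmetric, only the strict upper triangle
#' carries information: for `N` ROIs this gives `N*(N-1)/2` features (4005
#' for the 90-ROI cerebrum parcellation). Asymmetric regression-based
#' networks are symmetrized as `(W + W')/2` first.
#'
#' @param net an `fbn` fit or a square numeric weight matrix.
#' @return Numeric vector of length `N*(N-1)/2`, in [feature_index()] order.
#' @export
extract_upper_features <- function(net) {
  w <- if (inherits(net, "fbn")) net$weights else as.matrix(net)
  if (nrow(w) != ncol(w)) stop("weight matrix must be square")
  if (max(abs(w - t(w))) > 0) w <- (w + t(w)) / 2
  # row-major upper triangle == column-major lower triangle of the transpose
  tw <- t(w)
  tw[lower.tri(tw)]
}

#' Rebuild a symmetric weight matrix from an edge feature vector
#'
#' Inverse of [extract_upper_features()] (zero diagonal).
#' @param features vector of length `n*(n-1)/2`.
#' @param n number of ROIs.
#' @export
features_to_matrix <- function(features, n) {
  idx <- feature_index(n)
  if (length(features) != nrow(idx))
    stop("expected ", nrow(idx), " features for n = ", n, ", got ",
         length(features))
  w <- matrix(0, n, n)
  w[idx] <- features
  w + t(w)
}

#' Two-sample t-test feature selection
#'
#' Per-feature two-sided two-sample t-test between the two label groups;
#' features with `p < p_threshold` are kept. If no feature passes, the
#' `fallback_k` smallest-p features are returned instead so every
#' cross-validation fold stays classifiable. Features with zero variance in
#' both groups have no defined t statistic and are never selected.
#'
#' @param features numeric matrix, subjects in rows, edge features in columns.
#' @param labels binary vector (1 = positive/patient, 0 = negative/control);
#'   both classes need at least 2 members.
#' @param p_threshold significance threshold (default 0.01).
#' @param var_equal pooled-variance Student test if `TRUE` (default), Welch
#'   otherwise.
#' @param fallback_k number of smallest-p features kept when none passes.
#' @return Integer vector of selected column indices (possibly empty when no
#'   feature has a defined statistic).
#' @export
ttest_select <- function(features, labels, p_threshold = 0.01,
                         var_equal = TRUE, fallback_k = 10L) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present for feature selection")
  g1 <- labels == 1L
  n1 <- sum(g1)
  n0 <- sum(!g1)
  if (n1 < 2L || n0 < 2L)
    stop("each class needs at least 2 subjects for a t-test")
  p <- ttest_pvalues(features, g1, var_equal)
  sel <- which(!is.na(p) & p < p_threshold)
  if (!length(sel)) {
    ok <- which(!is.na(p))
    sel <- ok[order(p[ok])][seq_len(min(fallback_k, length(ok)))]
  }
  as.integer(sel)
}

# vectorised two-sample t p-values; NA where both group variances are zero
ttest_pvalues <- function(features, g1, var_equal = TRUE) {
  x1 <- features[g1, , drop = FALSE]
  x0 <- features[!g1, , drop = FALSE]
  n1 <- nrow(x1)
  n0 <- nrow(x0)
  m1 <- colMeans(x1)
  m0 <- colMeans(x0)
  v1 <- colSums(sweep(x1, 2L, m1, "-")^2) / (n1 - 1)
  v0 <- colSums(sweep(x0, 2L, m0, "-")^2) / (n0 - 1)
  degenerate <- v1 <= 0 & v0 <= 0
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- n1 + n0 - 2
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  tstat <- (m1 - m0) / se
  p <- 2 * pt(-abs(tstat), df)
  p[degenerate] <- NA_real_
  p
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, sensitivity (true-positive rate) and specificity (true-negative
#' rate): `ACC = (TP+TN)/(TP+TN+FP+FN)`, `SEN = TP/(TP+FN)`,
#' `SPE = TN/(TN+FP)`. Patients are the positive class throughout the
#' package.
#'
#' @param tp,fp,tn,fn nonnegative integer counts; both classes must be
#'   non-empty (`tp + fn > 0`, `tn + fp > 0`).
#' @return Named list with `acc`, `sen`, `spe`.
#' @export
#' @examples
#' confusion_metrics(tp = 33, fp = 17, tn = 30, fn = 12)
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (tp + fn == 0) stop("no positives: sensitivity undefined")
  if (tn + fp == 0) stop("no negatives: specificity undefined")
  list(acc = (tp + tn) / (tp + tn + fp + fn),
       sen = tp / (tp + fn),
       spe = tn / (tn + fp))
}
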