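# Diagnosis pipeline: per-subject FBN estimation -> upper-triangle features
# -> t-test selection -> linear SVM, evaluated by nested leave-one-out
# cross-validation with a grid search over the network penalty lambda1.
#
# Network estimation is per-subject and label-free, so the feature matrix for
# each candidate lambda1 is computed once and reused across folds; this is
# mathematically identical to re-estimating inside every fold. All *selection*
# and *fitting* steps see training rows only (leakage contract).

#' Candidate penalty grid
#'
#' The default grid searched by the nested cross-validation: 20 values
#' 0.05, 0.10, ..., 1.00.
#' @export
default_lambda_grid <- function() seq(0.05, 1, by = 0.05)

# features for every subject at one estimator setting
cohort_features <- function(ts_list, method, lambda1, prior, lambda2, nu,
                            alpha, max_iter, tol) {
  rows <- lapply(ts_list, function(ts) {
    fit <- suppressWarnings(fbn_fit(ts, method = method, prior = prior,
                                    lambda1 = lambda1, lambda2 = lambda2,
                                    nu = nu, alpha = alpha,
                                    max_iter = max_iter, tol = tol))
    extract_upper_features(fit)
  })
  do.call(rbind, rows)
}

svm_predict_fold <- function(xtr, ytr, xte, svm_C) {
  if (!ncol(xtr) || all(apply(xtr, 2L, function(col) length(unique(col)) == 1L))) {
    # degenerate features (e.g. W = 0 for every subject): majority vote,
    # ties broken toward the negative class
    maj <- if (sum(ytr == 1L) > sum(ytr == 0L)) 1L else 0L
    return(rep(maj, nrow(xte)))
  }
  fit <- e1071::svm(x = xtr, y = factor(ytr, levels = c(0L, 1L)),
                    kernel = "linear", cost = svm_C, scale = FALSE)
  as.integer(as.character(predict(fit, xte)))
}

#' Inner-loop penalty selection
#'
#' Leave-one-out cross-validation *within a training set* over candidate
#' `lambda1` values: for each candidate, each training subject is held out in
#' turn, features are re-selected by t-test on the remaining subjects, a
#' linear SVM is fitted and the held-out subject predicted. The candidate
#' with the highest inner accuracy wins; ties go to the smallest penalty
#' (sparser model).
#'
#' @param feats_by_lambda named list (names = candidate values as written by
#'   `as.character()`) of feature matrices restricted to the training
#'   subjects, one per candidate.
#' @param labels training labels (0/1).
#' @param p_threshold,var_equal,fallback_k passed to [ttest_select()].
#' @param svm_C linear-SVM cost.
#' @return The selected candidate value (numeric scalar).
#' @export
inner_param_select <- function(feats_by_lambda, labels, p_threshold = 0.01,
                               svm_C = 1, var_equal = TRUE, fallback_k = 10L) {
  grid <- as.numeric(names(feats_by_lambda))
  if (!length(grid)) stop("empty candidate grid")
  if (length(grid) == 1L) return(grid)
  labels <- as.integer(labels)
  n <- length(labels)
  acc <- vapply(seq_along(grid), function(g) {
    feats <- feats_by_lambda[[g]]
    correct <- vapply(seq_len(n), function(k) {
      tr <- setdiff(seq_len(n), k)
      sel <- ttest_select(feats[tr, , drop = FALSE], labels[tr],
                          p_threshold = p_threshold, var_equal = var_equal,
                          fallback_k = fallback_k)
      pred <- svm_predict_fold(feats[tr, sel, drop = FALSE], labels[tr],
                               feats[k, sel, drop = FALSE], svm_C)
      pred == labels[k]
    }, logical(1))
    mean(correct)
  }, numeric(1))
  best <- which(acc == max(acc))
  grid[best[which.min(grid[best])]]
}

#' Nested leave-one-out evaluation of an FBN estimator
#'
#' Full diagnosis pipeline: estimate each subject's FBN, take upper-triangle
#' edge weights as features, and for every held-out subject (outer LOOCV)
#' select the network penalty by an inner LOOCV grid search on the training
#' subjects, select features by two-sample t-test on the training subjects at
#' the chosen penalty, fit a linear SVM, and predict the held-out subject.
#' Aggregated predictions give the confusion counts and accuracy /
#' sensitivity / specificity. Deterministic given its inputs.
#'
#' @param ts_list list of subjects' time series ([fbn_ts] or matrices).
#' @param labels binary labels (1 = patient/positive, 0 = control); at least
#'   3 subjects per class.
#' @param method,prior,lambda2,nu,alpha,max_iter,tol estimator settings, as
#'   in [fbn_fit()] (`lambda1` comes from `grid`).
#' @param grid candidate `lambda1` values for the inner search (ignored for
#'   `method = "pc"`/`"pcand"`, which have no sparsity penalty).
#' @param p_threshold t-test selection threshold (default 0.01).
#' @param svm_C linear-SVM cost (default 1).
#' @param var_equal,fallback_k passed to [ttest_select()].
#' @return An object of class `fbn_loocv_report`: confusion counts `tp`,
#'   `fp`, `tn`, `fn`; metrics `acc`, `sen`, `spe`; `per_fold_selected_lambda`;
#'   `selected_feature_counts`; `predictions` and `labels`.
#' @export
fbn_loocv <- function(ts_list, labels,
                      method = c("sr", "pc", "pcand", "srand"),
                      grid = default_lambda_grid(),
                      prior = c("wishart", "l1"), lambda2 = 0.1, nu = NULL,
                      alpha = 1, max_iter = 50L, tol = 1e-4,
                      p_threshold = 0.01, svm_C = 1, var_equal = TRUE,
                      fallback_k = 10L) {
  method <- match.arg(method)
  prior <- match.arg(prior)
  labels <- as.integer(labels)
  n <- length(ts_list)
  if (length(labels) != n) stop("labels and ts_list lengths differ")
  if (sum(labels == 1L) < 3L || sum(labels == 0L) < 3L)
    stop("need at least 3 subjects per class")
  uses_lambda <- method %in% c("sr", "srand")
  if (uses_lambda && !length(grid)) stop("empty lambda1 grid")
  if (!uses_lambda) grid <- NA_real_

  feats_by_lambda <- lapply(grid, function(l1)
    cohort_features(ts_list, method, if (is.na(l1)) 0 else l1, prior,
                    lambda2, nu, alpha, max_iter, tol))
  names(feats_by_lambda) <- as.character(grid)

  pred <- integer(n)
  sel_lambda <- numeric(n)
  sel_count <- integer(n)
  for (k in seq_len(n)) {
    tr <- setdiff(seq_len(n), k)
    if (length(unique(labels[tr])) < 2L)
      stop("a class is absent from the training fold for subject ", k)
    best <- if (uses_lambda && length(grid) > 1L) {
      inner_param_select(lapply(feats_by_lambda, function(f)
        f[tr, , drop = FALSE]), labels[tr], p_threshold = p_threshold,
        svm_C = svm_C, var_equal = var_equal, fallback_k = fallback_k)
    } else grid[1L]
    feats <- feats_by_lambda[[match(best, grid)]]
    sel <- ttest_select(feats[tr, , drop = FALSE], labels[tr],
                        p_threshold = p_threshold, var_equal = var_equal,
                        fallback_k = fallback_k)
    pred[k] <- svm_predict_fold(feats[tr, sel, drop = FALSE], labels[tr],
                                feats[k, sel, drop = FALSE], svm_C)
    sel_lambda[k] <- best
    sel_count[k] <- length(sel)
  }
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  metrics <- confusion_metrics(tp, fp, tn, fn)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         acc = metrics$acc, sen = metrics$sen, spe = metrics$spe,
         per_fold_selected_lambda = sel_lambda,
         selected_feature_counts = sel_count,
         predictions = pred, labels = labels, method = method),
    class = "fbn_loocv_report")
}

#' @export
print.fbn_loocv_report <- function(x, ...) {
  cat("Nested LOOCV classification report (", x$method, ")\n", sep = "")
  cat(sprintf("  TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  ACC=%.4f SEN=%.4f SPE=%.4f\n", x$acc, x$sen, x$spe))
  lam <- x$per_fold_selected_lambda
  if (!all(is.na(lam))) {
    cat("  selected lambda1 frequency:\n")
    print(table(lam))
  }
  invisible(x)
}
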