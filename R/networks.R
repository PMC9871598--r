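# FBN estimators.
#
# All estimators work on centred, unit-norm columns, so cross-products are
# Pearson correlations. The noise-depressed variants alternate
#   W-step: baseline estimator on Y = Omega^{1/2} X
#   Omega-step: noise precision update on the residual R = X - X W
# starting from Omega = I, until the joint objective stabilises.

new_fbn <- function(weights, estimator, lambda1 = NULL, converged = TRUE,
                    n_iterations = 0L, omega = NULL, objective = NULL,
                    x = NULL, subject_id = "", call = NULL) {
  structure(
    list(weights = weights, estimator = estimator, lambda1 = lambda1,
         converged = converged, n_iterations = as.integer(n_iterations),
         omega = omega, objective = objective, x = x,
         subject_id = subject_id, call = call),
    class = "fbn")
}

#' Fit a functional brain network
#'
#' Front door to all network estimators. Given a subject's ROI time series
#' (T time points x N ROIs), estimates the N x N edge-weight matrix `W`:
#'
#' * `method = "pc"`: Pearson's correlation, `W = X'X` on normalized data.
#' * `method = "sr"`: sparse representation - per-ROI lasso regression on all
#'   other ROIs with penalty `lambda1` and a structural zero diagonal, i.e.
#'   `min ||X - XW||_F^2 + lambda1 ||W||_1, w_ii = 0`.
#' * `method = "pcand"` / `"srand"`: the adaptive-noise-depression variants,
#'   alternating the baseline estimator on the whitened series
#'   `Y = Omega^{1/2} X` with an update of the temporal noise precision
#'   `Omega` (shared across ROIs) on the residual `X - XW`, under either an
#'   L1 prior (graphical lasso, penalty `lambda2`) or a Wishart prior
#'   (closed-form update with degrees of freedom `nu` and scale
#'   `Sigma = alpha^{-1} I`).
#'
#' @param x ROI time series: [fbn_ts] or numeric T x N matrix. Centred and
#'   normalized internally when needed.
#' @param method one of `"pc"`, `"sr"`, `"pcand"`, `"srand"`.
#' @param prior noise prior for pcand/srand: `"wishart"` (default) or `"l1"`.
#' @param lambda1 nonnegative sparsity penalty on `W` (sr/srand). On
#'   normalized data any `lambda1 >= 2` yields `W = 0`.
#' @param lambda2 nonnegative sparsity penalty on `Omega` (L1 prior).
#' @param nu Wishart degrees of freedom, `> T - 1`; default `T`.
#' @param alpha Wishart prior scale (`Sigma = alpha^{-1} I`), positive.
#' @param max_iter maximum alternating iterations (pcand/srand).
#' @param tol relative joint-objective change declaring outer convergence.
#' @param lasso_tol,lasso_max_iter coordinate-descent control for the W-step.
#' @param omega_rescale if `TRUE`, rescale `Omega` to trace `T` after each
#'   update, decoupling the noise *shape* from the effective scale of
#'   `lambda1` in the next W-step. Default `FALSE` (faithful update).
#' @param keep_data keep the normalized series in the fit (needed by
#'   [residuals.fbn()]).
#'
#' @return An object of class `fbn` with components `weights` (N x N),
#'   `estimator` (`"pc"`, `"sr"`, `"pcand"`, `"srand_l1"`, `"srand_wishart"`),
#'   `lambda1`, `converged`, `n_iterations`, `omega` (a `noise_precision`,
#'   `NULL` for pc/sr), and `objective` (joint-objective trace recorded after
#'   every half-step, `NULL` for pc/sr).
#' @seealso [pc_network()], [sr_network()] for the baseline shortcuts;
#'   [joint_objective()] for the monitored objective.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40 * 6), 40, 6)
#' fit <- fbn_fit(x, method = "srand", prior = "wishart", lambda1 = 0.3)
#' fit
#' round(coef(fit), 2)
fbn_fit <- function(x, method = c("pc", "sr", "pcand", "srand"),
                    prior = c("wishart", "l1"),
                    lambda1 = 0.1, lambda2 = 0.1, nu = NULL, alpha = 1,
                    max_iter = 50L, tol = 1e-4,
                    lasso_tol = 1e-6, lasso_max_iter = 10000L,
                    omega_rescale = FALSE, keep_data = FALSE) {
  method <- match.arg(method)
  prior <- match.arg(prior)
  cl <- match.call()
  ts <- center_normalize(as_fbn_ts(x))
  if (lambda1 < 0) stop("`lambda1` must be nonnegative")

  fit <- switch(method,
    pc = {
      w <- pc_weights(ts$data)
      new_fbn(w, "pc", x = if (keep_data) ts$data else NULL,
              subject_id = ts$subject_id, call = cl)
    },
    sr = {
      w <- sr_weights(ts$data, lambda1, lasso_tol, lasso_max_iter)
      new_fbn(w, "sr", lambda1 = lambda1,
              x = if (keep_data) ts$data else NULL,
              subject_id = ts$subject_id, call = cl)
    },
    and_estimate(ts, wstep = if (method == "pcand") "pc" else "sr",
                 prior = prior, lambda1 = lambda1, lambda2 = lambda2,
                 nu = nu, alpha = alpha, max_iter = max_iter, tol = tol,
                 lasso_tol = lasso_tol, lasso_max_iter = lasso_max_iter,
                 omega_rescale = omega_rescale, keep_data = keep_data,
                 call = cl))
  fit
}

pc_weights <- function(x) {
  w <- crossprod(x)
  w <- (w + t(w)) / 2
  w <- pmin(pmax(w, -1), 1)
  diag(w) <- 1
  w
}

# lasso W-step; y need not have unit-norm columns (it does not, post-whitening)
sr_weights <- function(y, lambda1, lasso_tol = 1e-6, lasso_max_iter = 10000L,
                       w_init = NULL) {
  res <- cd_lasso_cols(y, lambda1, lasso_tol, as.integer(lasso_max_iter),
                       w_init)
  if (!res$converged)
    stop("lasso coordinate descent did not converge within ", lasso_max_iter,
         " iterations (max per-column sweeps used: ", max(res$iterations), ")")
  w <- res$W
  dimnames(w) <- list(colnames(y), colnames(y))
  w
}

#' Pearson-correlation network
#'
#' Convenience wrapper for `fbn_fit(x, method = "pc")`: the full-correlation
#' FBN `W = X'X` on centred, unit-norm data (unit diagonal, entries in
#' `[-1, 1]`).
#' @inheritParams fbn_fit
#' @return An `fbn` object.
#' @export
pc_network <- function(x) fbn_fit(x, method = "pc")

#' Sparse-representation network
#'
#' Convenience wrapper for `fbn_fit(x, method = "sr", lambda1 = lambda1)`:
#' each ROI is lasso-regressed on all others (zero diagonal enforced
#' structurally), an L1-stabilised surrogate for partial correlation.
#' @inheritParams fbn_fit
#' @return An `fbn` object (asymmetric in general; symmetrize for features
#'   via [extract_upper_features()]).
#' @export
sr_network <- function(x, lambda1, lasso_tol = 1e-6, lasso_max_iter = 10000L)
  fbn_fit(x, method = "sr", lambda1 = lambda1, lasso_tol = lasso_tol,
          lasso_max_iter = lasso_max_iter)

#' Joint objective of the noise-depressed estimators
#'
#' Evaluates the objective that the alternating SRAND updates descend:
#' with residual `R = X - XW` and `S = R R'`,
#' * L1 prior: `tr(R' Omega R) - N log|Omega| + lambda1 ||W||_1 +
#'   lambda2 ||Omega||_1` (elementwise, diagonal included);
#' * Wishart prior: `tr(Omega (S + alpha I)) - (N + nu) log|Omega| +
#'   lambda1 ||W||_1`.
#'
#' @param x normalized series ([fbn_ts] or matrix).
#' @param w N x N weight matrix.
#' @param omega `noise_precision` or T x T SPD matrix.
#' @inheritParams fbn_fit
#' @return Scalar objective value.
#' @export
joint_objective <- function(x, w, omega, prior = c("l1", "wishart"),
                            lambda1 = 0, lambda2 = 0, nu = NULL, alpha = 1) {
  prior <- match.arg(prior)
  xm <- if (inherits(x, "fbn_ts")) x$data else as.matrix(x)
  om <- omega_matrix(omega)
  n <- ncol(xm)
  tt <- nrow(xm)
  if (is.null(nu)) nu <- tt
  r <- xm - xm %*% w
  ch <- tryCatch(chol(om), error = function(e)
    stop("omega is not positive definite; log-determinant undefined"))
  logdet <- 2 * sum(log(diag(ch)))
  quad <- sum(r * (om %*% r))  # tr(R' Omega R)
  if (prior == "l1") {
    quad - n * logdet + lambda1 * sum(abs(w)) + lambda2 * sum(abs(om))
  } else {
    quad + alpha * sum(diag(om)) - (n + nu) * logdet + lambda1 * sum(abs(w))
  }
}

# Alternating noise-depression loop shared by PCAND and SRAND.
# Per iteration: W-step on the whitened data, then (unless the iteration
# budget is exhausted) the Omega-step on the residual. The objective trace
# records the value after each half-step; convergence compares the value
# after successive Omega-steps. PCAND's W-step is not a descent step on this
# objective, so for it the trace is monitoring-only.
and_estimate <- function(ts, wstep, prior, lambda1, lambda2, nu, alpha,
                         max_iter, tol, lasso_tol, lasso_max_iter,
                         omega_rescale, keep_data, call) {
  x <- ts$data
  tt <- nrow(x)
  n <- ncol(x)
  if (is.null(nu)) nu <- tt
  if (prior == "wishart" && nu <= tt - 1)
    stop("Wishart degrees of freedom must satisfy nu > T - 1")
  max_iter <- max(1L, as.integer(max_iter))
  l1_w <- if (wstep == "sr") lambda1 else 0
  omega <- new_noise_precision(diag(tt), prior = prior, params = list())
  trace <- numeric(0)
  converged <- FALSE
  prev <- NA_real_
  it <- 0L
  w <- NULL
  repeat {
    it <- it + 1L
    yts <- transform_data(ts, omega)
    if (wstep == "sr") {
      w <- sr_weights(yts$data, lambda1, lasso_tol, lasso_max_iter,
                      w_init = w)
    } else {
      w <- crossprod(yts$data)
      w <- (w + t(w)) / 2
    }
    trace <- c(trace, joint_objective(x, w, omega, prior = prior,
                                      lambda1 = l1_w, lambda2 = lambda2,
                                      nu = nu, alpha = alpha))
    if (it >= max_iter) {
      if (!converged)
        warning("reached max_iter = ", max_iter,
                " alternating iterations without meeting tol = ", tol)
      break
    }
    resid <- x - x %*% w
    omega <- switch(prior,
      l1 = omega_update_l1(resid, n, lambda2),
      wishart = omega_update_wishart(resid, n, nu = nu, alpha = alpha))
    if (omega_rescale)
      omega$omega <- omega$omega * (tt / sum(diag(omega$omega)))
    obj <- joint_objective(x, w, omega, prior = prior, lambda1 = l1_w,
                           lambda2 = lambda2, nu = nu, alpha = alpha)
    trace <- c(trace, obj)
    if (!is.na(prev) && abs(prev - obj) <= tol * max(abs(prev), 1e-10)) {
      converged <- TRUE
      break
    }
    prev <- obj
  }
  estimator <- if (wstep == "sr") paste0("srand_", prior) else "pcand"
  new_fbn(w, estimator,
          lambda1 = if (wstep == "sr") lambda1 else NULL,
          converged = converged, n_iterations = it, omega = omega,
          objective = trace, x = if (keep_data) x else NULL,
          subject_id = ts$subject_id, call = call)
}

#' @export
print.fbn <- function(x, ...) {
  n <- ncol(x$weights)
  offdiag <- x$weights[row(x$weights) != col(x$weights)]
  cat("Functional brain network (", x$estimator, ")\n", sep = "")
  if (nzchar(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  cat("  ", n, " ROIs, ", sum(offdiag != 0), "/", n * (n - 1),
      " nonzero off-diagonal weights\n", sep = "")
  if (!is.null(x$lambda1)) cat("  lambda1 =", x$lambda1, "\n")
  if (!is.null(x$omega))
    cat("  noise prior: ", x$omega$prior, "; ", x$n_iterations,
        " alternating iteration(s), ",
        if (x$converged) "converged" else "not converged", "\n", sep = "")
  invisible(x)
}

#' @export
summary.fbn <- function(object, n_top = 5L, ...) {
  w <- (object$weights + t(object$weights)) / 2
  feats <- extract_upper_features(w)
  idx <- feature_index(ncol(w))
  ord <- order(abs(feats), decreasing = TRUE)[seq_len(min(n_top, length(feats)))]
  out <- list(fit = object,
              weight_summary = summary(feats),
              top_edges = data.frame(roi_i = idx[ord, 1L], roi_j = idx[ord, 2L],
                                     weight = feats[ord]))
  class(out) <- "summary.fbn"
  out
}

#' @export
print.summary.fbn <- function(x, ...) {
  print(x$fit)
  cat("Upper-triangle edge weights:\n")
  print(x$weight_summary)
  cat("Largest-magnitude edges (1-based ROI indices):\n")
  print(x$top_edges, row.names = FALSE)
  invisible(x)
}

#' @export
coef.fbn <- function(object, ...) object$weights

#' Residuals of a fitted network
#'
#' Returns `X - X %*% W` on the normalized series, the residual the noise
#' model is estimated from. Requires the fit to have been made with
#' `keep_data = TRUE`.
#' @param object an `fbn` fit.
#' @param ... unused.
#' @export
residuals.fbn <- function(object, ...) {
  if (is.null(object$x))
    stop("fit was made with keep_data = FALSE; refit with keep_data = TRUE")
  object$x - object$x %*% object$weights
}

#' Plot a fitted network's adjacency matrix
#'
#' Heat-map of the (symmetrized) weight matrix, ROIs on both axes.
#' @param x an `fbn` fit.
#' @param symmetrize average `W` with its transpose before plotting.
#' @param ... passed to [graphics::image()].
#' @export
plot.fbn <- function(x, symmetrize = TRUE, ...) {
  w <- x$weights
  if (symmetrize) w <- (w + t(w)) / 2
  n <- ncol(w)
  graphics::image(seq_len(n), seq_len(n), t(w[n:1, , drop = FALSE]),
                  xlab = "ROI", ylab = "ROI",
                  main = paste0("FBN (", x$estimator, ")"), ...)
  invisible(x)
}
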