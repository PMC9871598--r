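# Temporal noise precision estimation.
#
# The noise model assumes the representation residuals r_i = x_i - X w_i share
# one T x T precision matrix Omega across ROIs. Writing S = R R' (R the T x N
# residual matrix), the negative log-likelihood in Omega is
#   tr(Omega S) - N log|Omega|,
# whose stationary point is Omega = N S^{-1} (the unregularized MLE). Because
# S has rank <= N < T in the typical fMRI regime, a prior is needed:
#  * L1 prior: adds lambda2 ||Omega||_1 and is solved as a graphical lasso on
#    the empirical covariance S/N with penalty lambda2/N.
#  * Wishart prior W(Omega | Sigma, nu) with Sigma = alpha^{-1} I: the
#    posterior mode is available in closed form,
#    Omega = (N + nu) (S + alpha I)^{-1}, always PD.

new_noise_precision <- function(omega, prior, params) {
  omega <- (omega + t(omega)) / 2
  structure(list(omega = omega, prior = prior, params = params),
            class = "noise_precision")
}

#' @export
print.noise_precision <- function(x, ...) {
  cat("Temporal noise precision (", nrow(x$omega), " x ", ncol(x$omega),
      "), prior = ", x$prior, "\n", sep = "")
  if (length(x$params))
    cat("  params:", paste(names(x$params), unlist(x$params),
                           sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Unregularized MLE of the temporal noise precision
#'
#' Returns `Omega = N * solve(S)` with `S = residual %*% t(residual)`, the
#' stationary point of the Gaussian noise log-likelihood. Only well defined
#' when `S` is nonsingular, which requires at least as many ROIs as time
#' points; it is provided mainly as a reference/oracle for the regularized
#' updates.
#'
#' @param residual T x N residual matrix `X - X %*% W`.
#' @param n_roi number of ROIs entering the likelihood (defaults to
#'   `ncol(residual)`).
#' @return A `noise_precision` object with `prior = "none"`.
#' @export
omega_mle <- function(residual, n_roi = ncol(residual)) {
  residual <- as.matrix(residual)
  s <- tcrossprod(residual)
  ch <- tryCatch(chol(s), error = function(e) NULL)
  if (is.null(ch) || rcond(s) < 1e-12)
    stop("residual Gram matrix S is singular or near-singular (rank <= ",
         min(dim(residual)), " < ", nrow(s), "); the unregularized noise ",
         "MLE is ill-posed - use a prior (omega_update_l1 or ",
         "omega_update_wishart)")
  new_noise_precision(n_roi * chol2inv(ch), prior = "none", params = list())
}

#' Noise precision update under the L1 (sparsity) prior
#'
#' Solves `min tr(Omega S) - N log|Omega| + lambda2 ||Omega||_1` (elementwise
#' L1 including the diagonal) by mapping it to the classical graphical lasso
#' with empirical covariance `S / N` and penalty `lambda2 / N`.
#'
#' @inheritParams omega_mle
#' @param lambda2 nonnegative sparsity penalty on `Omega`, on the joint
#'   objective's scale. `lambda2 = 0` falls back to [omega_mle()] (and so
#'   requires nonsingular `S`).
#' @param tol graphical-lasso convergence threshold (relative to the mean
#'   absolute off-diagonal of `S/N`).
#' @param max_iter maximum outer sweeps of the graphical lasso.
#' @return A `noise_precision` with `prior = "l1"`; symmetric PD.
#' @export
omega_update_l1 <- function(residual, n_roi = ncol(residual), lambda2,
                            tol = 1e-5, max_iter = 1000L) {
  residual <- as.matrix(residual)
  if (lambda2 < 0) stop("lambda2 must be nonnegative")
  if (lambda2 == 0) {
    out <- omega_mle(residual, n_roi)
    out$prior <- "l1"
    out$params <- list(lambda2 = 0)
    return(out)
  }
  s <- tcrossprod(residual)
  om <- glasso_cpp(s / n_roi, lambda2 / n_roi, tol, as.integer(max_iter),
                   as.integer(max_iter))
  if (!all(is.finite(om)) || min(eigen(om, symmetric = TRUE,
                                       only.values = TRUE)$values) <= 0) {
    warning("ill-conditioned residual Gram matrix; adding ridge ",
            "1e-8 * tr(S)/T to S and re-solving")
    ridge <- 1e-8 * sum(diag(s)) / nrow(s)
    s <- s + diag(ridge, nrow(s))
    om <- glasso_cpp(s / n_roi, lambda2 / n_roi, tol, as.integer(max_iter),
                     as.integer(max_iter))
  }
  new_noise_precision(om, prior = "l1", params = list(lambda2 = lambda2))
}

#' Noise precision update under the Wishart prior
#'
#' Closed-form posterior mode `Omega = (N + nu) * solve(S + alpha * I)` for a
#' Wishart prior `W(Omega | Sigma, nu)` with isotropic scale
#' `Sigma = alpha^{-1} I`. The ridge `alpha * I` makes the update well posed
#' for any residual, including the rank-deficient `T > N` regime.
#'
#' @inheritParams omega_mle
#' @param nu degrees of freedom; must exceed `T - 1` (default: `T`, the
#'   smallest integer satisfying the constraint).
#' @param alpha positive prior scale; larger values shrink `Omega` toward
#'   `(N + nu)/alpha * I`.
#' @return A `noise_precision` with `prior = "wishart"`; symmetric PD.
#' @export
omega_update_wishart <- function(residual, n_roi = ncol(residual),
                                 nu = nrow(as.matrix(residual)), alpha = 1) {
  residual <- as.matrix(residual)
  tt <- nrow(residual)
  if (!is.numeric(nu) || nu <= tt - 1)
    stop("Wishart degrees of freedom must satisfy nu > T - 1 (T = ", tt,
         ", nu = ", nu, ")")
  if (!is.numeric(alpha) || alpha <= 0)
    stop("`alpha` must be positive")
  s <- tcrossprod(residual) + diag(alpha, tt)
  om <- (n_roi + nu) * chol2inv(chol(s))
  new_noise_precision(om, prior = "wishart",
                      params = list(nu = nu, alpha = alpha))
}
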