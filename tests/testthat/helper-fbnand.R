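# Shared fixtures and independent oracles for the test suite.

# random centred/unit-norm series
rand_normalized <- function(n_time, n_roi, seed) {
  set.seed(seed)
  center_normalize(matrix(rnorm(n_time * n_roi), n_time, n_roi))
}

# Independent lasso oracle: ISTA (proximal gradient) for
#   min_w ||y - A w||^2 + lambda ||w||_1
# deliberately a different algorithm from the package's coordinate descent.
ista_lasso <- function(y, a, lambda, iters = 20000L) {
  lip <- 2 * max(eigen(crossprod(a), symmetric = TRUE,
                       only.values = TRUE)$values)
  step <- 1 / lip
  w <- rep(0, ncol(a))
  for (k in seq_len(iters)) {
    grad <- 2 * crossprod(a, a %*% w - y)
    z <- w - step * grad
    w_new <- sign(z) * pmax(abs(z) - step * lambda, 0)
    if (max(abs(w_new - w)) < 1e-12) {
      w <- w_new
      break
    }
    w <- w_new
  }
  w
}

# full lasso network via the ISTA oracle (zero diagonal by construction)
ista_network <- function(x, lambda) {
  n <- ncol(x)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    a <- x[, -i, drop = FALSE]
    w[-i, i] <- ista_lasso(x[, i], a, lambda)
  }
  w
}

# Independent numeric minimizer of tr(Omega M) - c * log|Omega| over SPD
# Omega, parameterised by the Cholesky factor (oracle for the closed-form
# noise updates).
numeric_omega_min <- function(m, c_logdet, start = NULL) {
  p <- nrow(m)
  if (is.null(start)) start <- c_logdet * solve(m + 0.1 * diag(p))
  l0 <- t(chol(start))
  th0 <- l0[lower.tri(l0, diag = TRUE)]
  obj <- function(th) {
    l <- matrix(0, p, p)
    l[lower.tri(l, diag = TRUE)] <- th
    om <- l %*% t(l)
    val <- sum(om * m) - c_logdet * as.numeric(determinant(om)$modulus)
    if (!is.finite(val)) return(1e12)
    val
  }
  opt <- stats::optim(th0, obj, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-14))
  l <- matrix(0, p, p)
  l[lower.tri(l, diag = TRUE)] <- opt$par
  l %*% t(l)
}

rel_frob <- function(a, b) norm(a - b, "F") / max(norm(b, "F"), 1e-300)
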