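test_that("PC network matches hand-computed correlations", {
  # duplicate columns correlate perfectly; third column for the derived case
  m <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 3, 2))
  w <- coef(pc_network(m))
  expect_equal(w[1, 2], 1)
  expect_equal(w[1, 3], 0.5)       # direct evaluation of the PC formula
  expect_equal(diag(w), rep(1, 3), ignore_attr = TRUE)
  expect_identical(w, t(w))
  expect_true(all(w >= -1 & w <= 1))

  # orthogonal after centering
  m2 <- cbind(c(-1, 0, 1, 0), c(0, -1, 0, 1))
  expect_equal(coef(pc_network(m2))[1, 2], 0, tolerance = 1e-12)
})

test_that("SR with lambda1 = 0 reproduces least squares, large lambda1 kills W", {
  ts <- rand_normalized(40, 5, seed = 21)
  w0 <- coef(sr_network(ts, lambda1 = 0))
  for (i in 1:5) {
    a <- ts$data[, -i]
    beta <- solve(crossprod(a), crossprod(a, ts$data[, i]))
    expect_equal(unname(w0[-i, i]), c(beta), tolerance = 1e-5)
  }
  expect_equal(diag(w0), rep(0, 5), ignore_attr = TRUE)
  # zero-solution threshold on normalized data: lambda1 >= 2 max|x_j'x_i|
  expect_identical(unname(coef(sr_network(ts, lambda1 = 2))), matrix(0, 5, 5))
  expect_identical(unname(coef(sr_network(ts, lambda1 = 2.7))), matrix(0, 5, 5))
})

test_that("SR recovers a duplicated ROI as the strongest edge", {
  set.seed(31)
  base <- matrix(rnorm(60), 30, 2)
  m <- cbind(base[, 1], base[, 2], base[, 1])  # ROI 3 duplicates ROI 1
  w <- coef(sr_network(m, lambda1 = 0.05))
  off <- abs(w[row(w) != col(w)])
  expect_equal(sort(c(abs(w[1, 3]), abs(w[3, 1])), decreasing = TRUE),
               sort(off, decreasing = TRUE)[1:2])
})

test_that("coordinate descent agrees with an independent proximal-gradient solver", {
  for (seed in c(5, 6)) {
    ts <- rand_normalized(35, 7, seed = seed)
    for (lam in c(0.05, 0.3, 0.8)) {
      w_cd <- coef(sr_network(ts, lambda1 = lam))
      w_ista <- ista_network(ts$data, lam)
      expect_lt(max(abs(w_cd - w_ista)), 1e-4)
    }
  }
})

test_that("SPD square root squares back to its argument", {
  expect_equal(matrix_sqrt_spd(diag(3)), diag(3))
  expect_equal(matrix_sqrt_spd(diag(c(4, 9))), diag(c(2, 3)))
  set.seed(41)
  a <- matrix(rnorm(36), 6, 6)
  m <- crossprod(a)
  r <- matrix_sqrt_spd(m)
  expect_lt(rel_frob(r %*% r, m), 1e-8)
  expect_identical(r, t(r))
  expect_error(matrix_sqrt_spd(diag(c(1, -0.5))), "not positive semidefinite")
  expect_error(matrix_sqrt_spd(matrix(c(1, 0.5, 0, 1), 2, 2)), "symmetric")
})

test_that("whitening with the identity is a no-op and preserves the quadratic form", {
  ts <- rand_normalized(20, 4, seed = 51)
  y <- transform_data(ts, diag(20))
  expect_equal(y$data, ts$data, tolerance = 1e-12)
  expect_false(y$normalized)
  y4 <- transform_data(ts, 4 * diag(20))
  expect_equal(y4$data, 2 * ts$data, tolerance = 1e-12)

  # residual quadratic form identity on random W and SPD Omega
  set.seed(52)
  for (rep in 1:5) {
    a <- matrix(rnorm(400), 20, 20)
    omega <- crossprod(a) / 20 + diag(20)
    w <- matrix(rnorm(16), 4, 4)
    diag(w) <- 0
    y <- transform_data(ts, omega)$data
    lhs <- sum((y - y %*% w)^2)
    r <- ts$data - ts$data %*% w
    rhs <- sum(r * (omega %*% r))
    expect_lt(abs(lhs - rhs) / abs(rhs), 1e-8)
  }
})

test_that("joint objective reproduces closed-form values at W = 0, Omega = I", {
  ts <- rand_normalized(18, 6, seed = 61)
  w0 <- matrix(0, 6, 6)
  expect_equal(joint_objective(ts, w0, diag(18), prior = "l1",
                               lambda1 = 0.3, lambda2 = 0.25),
               6 + 0.25 * 18, tolerance = 1e-10)
  expect_equal(joint_objective(ts, w0, diag(18), prior = "wishart",
                               lambda1 = 0.3, nu = 18, alpha = 0.7),
               6 + 0.7 * 18, tolerance = 1e-10)
  # a nonzero SR step strictly decreases the objective
  w1 <- coef(sr_network(ts, lambda1 = 0.1))
  expect_gt(sum(abs(w1)), 0)
  expect_lt(joint_objective(ts, w1, diag(18), prior = "l1",
                            lambda1 = 0.1, lambda2 = 0.25),
            joint_objective(ts, w0, diag(18), prior = "l1",
                            lambda1 = 0.1, lambda2 = 0.25))
  expect_error(joint_objective(ts, w0, matrix(0, 18, 18), prior = "l1"),
               "positive definite")
})

test_that("one alternating iteration reduces to the baseline estimators", {
  ts <- rand_normalized(30, 8, seed = 71)
  w_sr <- coef(sr_network(ts, lambda1 = 0.4))
  for (pr in c("l1", "wishart")) {
    fit <- suppressWarnings(fbn_fit(ts, method = "srand", prior = pr,
                                    lambda1 = 0.4, max_iter = 1))
    expect_lt(max(abs(coef(fit) - w_sr)), 1e-5)
    expect_equal(fit$n_iterations, 1L)
  }
  w_pc <- coef(pc_network(ts))
  fit_pc <- suppressWarnings(fbn_fit(ts, method = "pcand", max_iter = 1))
  expect_lt(max(abs(coef(fit_pc) - w_pc)), 1e-6)
  expect_warning(fbn_fit(ts, method = "srand", lambda1 = 0.4, max_iter = 1),
                 "max_iter")
})

test_that("alternating SRAND descends its joint objective", {
  for (seed in c(81, 82, 83)) {
    set.seed(seed)
    ts <- center_normalize(matrix(rnorm(32 * 7), 32, 7))
    for (pr in c("l1", "wishart")) {
      fit <- suppressWarnings(fbn_fit(ts, method = "srand", prior = pr,
                                      lambda1 = 0.3, lambda2 = 0.1,
                                      max_iter = 8))
      expect_true(all(diff(fit$objective) <= 1e-8))
    }
  }
})

test_that("PCAND with a fixed isotropic Omega rescales the PC weights", {
  ts <- rand_normalized(22, 5, seed = 91)
  for (cc in c(0.5, 3)) {
    y <- transform_data(ts, cc * diag(22))$data
    expect_equal(crossprod(y), cc * crossprod(ts$data), tolerance = 1e-10)
  }
})

test_that("PCAND keeps Omega symmetric positive definite at every iteration", {
  ts <- rand_normalized(25, 6, seed = 101)
  omega <- diag(25)
  for (it in 1:10) {
    y <- transform_data(ts, omega)$data
    w <- crossprod(y)
    w <- (w + t(w)) / 2
    np <- omega_update_wishart(ts$data - ts$data %*% w, 6)
    omega <- np$omega
    expect_lt(max(abs(omega - t(omega))), 1e-8)
    expect_gt(min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  fit <- suppressWarnings(fbn_fit(ts, method = "pcand", prior = "wishart",
                                  max_iter = 10))
  expect_identical(fit$estimator, "pcand")
  expect_gt(min(eigen(fit$omega$omega, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
})

test_that("fit object methods expose weights and residuals coherently", {
  ts <- rand_normalized(30, 5, seed = 111)
  fit <- fbn_fit(ts, method = "sr", lambda1 = 0.2, keep_data = TRUE)
  expect_s3_class(fit, "fbn")
  expect_identical(coef(fit), fit$weights)
  expect_equal(residuals(fit), ts$data - ts$data %*% fit$weights)
  expect_output(print(fit), "sr")
  expect_output(print(summary(fit)), "edge")
  fit2 <- fbn_fit(ts, method = "sr", lambda1 = 0.2)
  expect_error(residuals(fit2), "keep_data")
})
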