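test_that("ground truth and cohorts are deterministic given the seed", {
  cfg <- synth_config(n_roi = 12, n_time = 30, n_per_group = 3,
                      effect_size = 0.5, n_effect_edges = 4, seed = 42)
  expect_identical(make_ground_truth(cfg), make_ground_truth(cfg))
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(lapply(c1$ts, `[[`, "data"), lapply(c2$ts, `[[`, "data"))
  expect_identical(c1$labels, rep(c(1L, 0L), each = 3))
  expect_identical(c1$subject_ids, sprintf("sub-%03d", 1:6))
})

test_that("ground truth has the requested structure", {
  cfg <- synth_config(n_roi = 20, n_time = 25, edge_density = 0.1,
                      ar_rho = 0, effect_size = 0, seed = 1)
  gt <- make_ground_truth(cfg)
  expect_identical(gt$temporal_noise_cov, diag(25))  # iid noise when rho = 0
  p <- gt$roi_precision
  expect_identical(p, t(p))
  expect_gt(min(eigen(p, symmetric = TRUE, only.values = TRUE)$values), 0)
  # support = off-diagonal nonzeros
  nz <- which(p != 0 & upper.tri(p), arr.ind = TRUE)
  expect_equal(nrow(gt$support), nrow(nz))
  # effect_size = 0 leaves the patient precision untouched
  expect_identical(gt$roi_precision_patient, gt$roi_precision)

  # edge count matches the binomial expectation over many seeds
  counts <- vapply(1:100, function(s)
    nrow(make_ground_truth(synth_config(n_roi = 20, n_time = 25,
                                        edge_density = 0.1, effect_size = 0,
                                        seed = s))$support), numeric(1))
  expect_gt(mean(counts), 19 - 4 * 1.31)  # 190 * 0.1 +- 4 SE
  expect_lt(mean(counts), 19 + 4 * 1.31)
})

test_that("AR(1) covariance is realized in the simulated noise", {
  cfg <- synth_config(n_roi = 8, n_time = 400, n_per_group = 1,
                      edge_density = 0.1, ar_rho = 0.9, noise_scale = 25,
                      effect_size = 0, seed = 5)
  gt <- make_ground_truth(cfg)
  set.seed(6)
  ts <- simulate_subject(gt, group = 0)
  # noise dominates at sigma = 25; lag-1 autocorrelation should be near rho
  ac <- apply(ts$data, 2, function(v) cor(v[-1], v[-length(v)]))
  expect_equal(mean(ac), 0.9, tolerance = 0.05)
})

test_that("clean draws are consistent with the ROI precision at large T", {
  cfg_small <- synth_config(n_roi = 8, n_time = 300, edge_density = 0.15,
                            noise_scale = 0, effect_size = 0, seed = 9)
  cfg_big <- synth_config(n_roi = 8, n_time = 6000, edge_density = 0.15,
                          noise_scale = 0, effect_size = 0, seed = 9)
  err <- vapply(list(cfg_small, cfg_big), function(cfg) {
    gt <- make_ground_truth(cfg)
    set.seed(10)
    ts <- simulate_subject(gt, group = 0)
    emp_prec <- solve(crossprod(ts$data) / nrow(ts$data))
    rel_frob(emp_prec, gt$roi_precision)
  }, numeric(1))
  expect_lt(err[2], err[1])     # error shrinks with T
  expect_lt(err[2], 0.15)
})

test_that("recovery scoring behaves at its extremes and at chance", {
  cfg <- synth_config(n_roi = 12, n_time = 30, edge_density = 0.2,
                      effect_size = 0, seed = 20)
  gt <- make_ground_truth(cfg)
  k <- nrow(gt$support)
  # perfect prediction: use the truth itself
  w_true <- gt$roi_precision
  diag(w_true) <- 0
  expect_equal(recovery_score(w_true, gt)$f1, 1)
  # disjoint prediction: put weight only on non-edges
  idx <- feature_index(12)
  feats <- rep(0, nrow(idx))
  non_edges <- setdiff(seq_len(nrow(idx)),
                       match(paste(gt$support[, 1], gt$support[, 2]),
                             paste(idx[, 1], idx[, 2])))
  feats[non_edges[seq_len(k)]] <- 1
  expect_equal(recovery_score(features_to_matrix(feats, 12), gt)$f1, 0)
  expect_error(recovery_score(w_true, gt, top_k = 1000), "top_k")

  # random weights: expected precision ~ edge density
  set.seed(21)
  prec <- vapply(1:100, function(r) {
    w <- matrix(rnorm(144), 12, 12)
    recovery_score(w + t(w), gt, top_k = k)$precision
  }, numeric(1))
  density_true <- k / nrow(idx)
  expect_lt(abs(mean(prec) - density_true), 0.04)  # ~4 SE of the mean
})

test_that("Wishart-prior alternating runs converge at realistic sizes", {
  conv <- vapply(1:10, function(s) {
    cfg <- synth_config(n_roi = 15, n_time = 120, n_per_group = 1,
                        edge_density = 0.1, ar_rho = 0.6, noise_scale = 0.5,
                        effect_size = 0, seed = s)
    gt <- make_ground_truth(cfg)
    set.seed(cfg$seed + 1L)
    ts <- simulate_subject(gt, group = 0)
    fit <- suppressWarnings(fbn_fit(ts, method = "srand", prior = "wishart",
                                    lambda1 = 0.3))
    fit$converged
  }, logical(1))
  expect_gte(mean(conv), 0.8)
})
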