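test_that("error draws honour the residual bounds and degenerate cases", {
  expect_identical(draw_error(c(0, 0, 0, 0)), 0)
  set.seed(1)
  resid <- rnorm(20)
  s <- sd(resid)
  set.seed(42)
  draws <- replicate(500, draw_error(resid))
  expect_true(all(abs(draws) <= 1.96 * s))
  # scale equivariance: same seed, scaled residuals -> scaled draw
  set.seed(7); a <- draw_error(resid)
  set.seed(7); b <- draw_error(3 * resid)
  expect_equal(b, 3 * a, tolerance = 1e-12)
  expect_error(draw_error(0.5), "at least 2")
  # the alternative error models stay inside their bounds too
  set.seed(9)
  u <- replicate(200, draw_error(resid, method = "uniform"))
  expect_true(all(abs(u) <= 1.96 * s))
  q <- quantile(resid, c(0.025, 0.975))
  set.seed(9)
  e <- replicate(200, draw_error(resid, method = "empirical"))
  expect_true(all(e >= q[1] & e <= q[2]))
})

test_that("interpolation passes observed values through and fills the rest", {
  set.seed(14)
  gt <- q60_profile(runif(25, 4, 12))
  obs <- downsample(gt, build_scheme("Q120"))
  fit <- fit_polynomial(obs, 3)
  ip <- interpolate_once(fit, obs, gt$times, seed = 101L)
  expect_length(ip$times, 25L)
  expect_identical(sum(!ip$is_observed), 12L)
  expect_identical(ip$values[ip$is_observed], obs$values)
  # deterministic given the seed
  again <- interpolate_once(fit, obs, gt$times, seed = 101L)
  expect_identical(ip$values, again$values)
  # nothing to fill when the target equals the observed grid
  null_ip <- interpolate_once(fit, obs, obs$times, seed = 5L)
  expect_identical(null_ip$values, obs$values)
  expect_true(all(null_ip$is_observed))
  # a dense Q10 target works the same way
  q10 <- seq(0, 1440, by = 10)
  dense <- interpolate_once(fit, obs, q10, seed = 3L)
  expect_length(dense$times, 145L)
  expect_identical(sum(!dense$is_observed), 132L)
  expect_error(interpolate_once(fit, obs, seq(30, 1410, by = 60), 1L),
               "subset")
})

test_that("kde_mode matches an independent fine-grid oracle", {
  expect_identical(kde_mode(rep(2.5, 10)), 2.5)
  # a point mass with one outlier peaks near the mass, not the mean
  v <- c(0, 0, 0, 0, 0, 10)
  m <- kde_mode(v)
  expect_lt(abs(m - 0), bw.nrd0(v))
  expect_gt(abs(m - mean(v)), abs(m))
  expect_equal(m, kde_mode_oracle(v), tolerance = bw.nrd0(v) / 10)
  # symmetric unimodal samples peak near the median
  set.seed(77)
  for (i in 1:5) {
    z <- rnorm(500, mean = 5)
    expect_lt(abs(kde_mode(z) - median(z)), bw.nrd0(z))
    expect_equal(kde_mode(z), kde_mode_oracle(z),
                 tolerance = bw.nrd0(z) / 5)
  }
  expect_error(kde_mode(3), "2 finite")
})

test_that("a noiseless polynomial truth collapses the ensemble", {
  truth <- known_polynomial_cohort(c(8, 2, -3, 1), noise_sd = 0,
                                   n_subjects = 1L)[[1L]]
  gt_fit <- fit_polynomial(truth, 3)
  obs <- downsample(truth, build_scheme("Q120"))
  fit <- fit_polynomial(obs, 3)
  ens <- interpolation_ensemble(fit, obs, gt_fit, truth$times,
                                n_iter = 50L, master_seed = 4L)
  expect_equal(ens$rmse_values, rep(0, 50L), tolerance = 1e-9)
  expect_equal(ens$r2_values, rep(1, 50L), tolerance = 1e-12)
  expect_equal(ens$r2_peak, 1, tolerance = 1e-12)
  expect_equal(ens$rmse_peak, 0, tolerance = 1e-9)
})

test_that("ensembles are deterministic and peaks stay in range", {
  set.seed(31)
  gt <- q60_profile(runif(25, 4, 12))
  gt_fit <- fit_polynomial(gt, 3)
  obs <- downsample(gt, build_scheme("Q240"))
  fit <- fit_polynomial(obs, 3)
  e1 <- interpolation_ensemble(fit, obs, gt_fit, gt$times,
                               n_iter = 60L, master_seed = 9L)
  e2 <- interpolation_ensemble(fit, obs, gt_fit, gt$times,
                               n_iter = 60L, master_seed = 9L)
  expect_identical(e1$seeds, e2$seeds)
  expect_identical(e1$r2_values, e2$r2_values)
  expect_identical(e1$rmse_values, e2$rmse_values)
  expect_identical(e1$optimal_seed, e2$optimal_seed)
  expect_gte(e1$r2_peak, min(e1$r2_values))
  expect_lte(e1$r2_peak, max(e1$r2_values))
  expect_gte(e1$rmse_peak, min(e1$rmse_values))
  expect_lte(e1$rmse_peak, max(e1$rmse_values))
  expect_error(interpolation_ensemble(fit, obs, gt_fit, gt$times,
                                      n_iter = 1L, master_seed = 1L),
               "n_iter")
})

test_that("the optimal iteration regenerates bit-identically", {
  set.seed(55)
  gt <- q60_profile(runif(25, 4, 12))
  gt_fit <- fit_polynomial(gt, 2)
  obs <- downsample(gt, build_scheme("Q360"))
  fit <- fit_polynomial(obs, 2)
  ens <- interpolation_ensemble(fit, obs, gt_fit, gt$times,
                                n_iter = 40L, master_seed = 17L)
  opt <- regenerate_optimal(fit, obs, gt$times, ens)
  expect_identical(opt$iteration_seed, ens$optimal_seed)
  ref <- predict(gt_fit, gt$times)
  r2 <- 1 - sum((ref - opt$values)^2) / sum((ref - mean(ref))^2)
  rmse <- sqrt(mean((ref - opt$values)^2))
  expect_identical(r2, ens$r2_values[ens$optimal_index])
  expect_identical(rmse, ens$rmse_values[ens$optimal_index])
  # regenerating twice gives the same profile; observed points intact
  opt2 <- regenerate_optimal(fit, obs, gt$times, ens)
  expect_identical(opt$values, opt2$values)
  expect_identical(opt$values[opt$is_observed], obs$values)
  # mismatched inputs are refused
  other <- fit_polynomial(obs, 3)
  expect_error(regenerate_optimal(other, obs, gt$times, ens),
               "do not match")
})

test_that("ensemble error scales with the generating noise", {
  mean_rmse <- function(noise_sd, seed) {
    prof <- known_polynomial_cohort(c(8, 2, -3, 1), noise_sd = noise_sd,
                                    n_subjects = 1L, seed = seed)[[1L]]
    gt_fit <- fit_polynomial(prof, 3)
    obs <- downsample(prof, build_scheme("Q120"))
    fit <- fit_polynomial(obs, 3)
    ens <- interpolation_ensemble(fit, obs, gt_fit, prof$times,
                                  n_iter = 40L, master_seed = seed)
    mean(ens$rmse_values)
  }
  seeds <- 1:20
  hi <- vapply(seeds, function(s) mean_rmse(1.0, s), numeric(1))
  lo <- vapply(seeds, function(s) mean_rmse(0.5, s), numeric(1))
  expect_lt(mean(lo), mean(hi))
})

test_that("ensembles serialize to JSON with their seeds and peaks", {
  set.seed(2)
  gt <- q60_profile(runif(25, 4, 12))
  gt_fit <- fit_polynomial(gt, 2)
  obs <- downsample(gt, build_scheme("Q360"))
  fit <- fit_polynomial(obs, 2)
  ens <- interpolation_ensemble(fit, obs, gt_fit, gt$times,
                                n_iter = 10L, master_seed = 3L)
  parsed <- jsonlite::fromJSON(ensemble_to_json(ens))
  expect_identical(parsed$optimal_seed, ens$optimal_seed)
  expect_equal(parsed$rmse_values, ens$rmse_values, tolerance = 1e-12)
})
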