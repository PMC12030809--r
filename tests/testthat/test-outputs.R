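test_that("trapezoidal 24 h output is exact on simple shapes", {
  expect_equal(total_output(flat_profile(1))$auc, 1440)
  ramp <- q60_profile(10 * q60_minutes() / 1440)
  expect_equal(total_output(ramp)$auc, 7200)
  # additivity across an interior grid point
  set.seed(6)
  prof <- q60_profile(runif(25, 2, 9))
  expect_equal(total_output(prof)$auc,
               total_output(prof, window = c(0, 720))$auc +
                 total_output(prof, window = c(720, 1440))$auc,
               tolerance = 1e-9)
  # unit variants
  expect_equal(total_output(flat_profile(1), rule = "trapezoid_hours")$auc,
               24)
  expect_equal(total_output(flat_profile(1), rule = "sum")$auc, 25)
  short <- cortisol_profile("S", "rest", "serum", c(60, 1440), c(1, 1))
  expect_error(total_output(short), "endpoints")
})

test_that("output estimates carry their provenance", {
  est <- total_output(flat_profile(2))
  expect_identical(est$source, "observed")
  expect_true(is.na(est$degree))
  gt <- q60_profile(seq(4, 10, length.out = 25))
  obs <- downsample(gt, build_scheme("Q120"))
  fit <- fit_polynomial(obs, 2)
  ip <- interpolate_once(fit, obs, gt$times, seed = 1L)
  est_i <- total_output(ip)
  expect_identical(est_i$source, "interpolated")
  expect_identical(est_i$degree, 2L)
  expect_identical(est_i$scheme, "Q120")
})

test_that("paired TOST matches the closed-form paired-t oracle", {
  x <- c(10, 11, 12, 13)
  y <- c(10.5, 11.2, 12.4, 12.9)
  res <- tost_paired(x, y, tost_config())
  # frozen values from the closed-form paired-t computation
  expect_equal(res$estimate, 0.0229691116, tolerance = 1e-6)
  expect_equal(res$ci_lower, -0.0052845559, tolerance = 1e-6)
  expect_equal(res$ci_upper, 0.0512227791, tolerance = 1e-6)
  expect_equal(res$p_lower, 9.316260342e-05, tolerance = 1e-6)
  expect_equal(res$p_upper, 0.000161431583, tolerance = 1e-6)
  expect_equal(res$cohens_d, 0.9565955868, tolerance = 1e-6)
  expect_true(res$equivalent)
})

test_that("TOST declares equivalence if and only if the CI is inside", {
  set.seed(2024)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    x <- exp(rnorm(n, log(100), 0.3))
    shift <- runif(1, -0.5, 0.5)
    y <- x * exp(shift + rnorm(n, 0, runif(1, 0.01, 0.3)))
    res <- tost_paired(x, y, tost_config())
    inside <- res$ci_lower > -0.25 && res$ci_upper < 0.25
    expect_identical(res$equivalent, inside)
    expect_identical(res$equivalent,
                     max(res$p_lower, res$p_upper) < 0.05)
    expect_lte(res$ci_lower, res$estimate)
    expect_gte(res$ci_upper, res$estimate)
  }
})

test_that("TOST boundary behaviour follows the shift", {
  set.seed(5)
  x <- exp(rnorm(8, log(10000), 0.2))
  near <- x * exp(rnorm(8, 0, 0.01))
  expect_true(tost_paired(x, near, tost_config())$equivalent)
  far <- x * exp(0.5 + rnorm(8, 0, 0.05))
  expect_false(tost_paired(x, far, tost_config())$equivalent)
  expect_error(tost_paired(c(-1, 2, 3), c(1, 2, 3), tost_config()),
               "positive")
  expect_error(tost_paired(1:2, 1:2, tost_config()), "n >= 3")
  # raw-difference and SMD-bound variants run on the same data
  raw <- tost_paired(x, near, tost_config(epsilon = 500,
                                          log_transform = FALSE))
  expect_true(raw$equivalent)
  smd <- tost_paired(x, near, tost_config(bounds = "smd", epsilon = 3))
  expect_identical(smd$epsilon_used > 0, TRUE)
})

test_that("Cohen's d for paired differences is the standardized mean", {
  expect_error(cohens_d_paired(c(0.1, 0.1, 0.1)), "zero sd")
  expect_identical(cohens_d_paired(c(-1, 1)), 0)
  expect_equal(cohens_d_paired(c(1, 2, 3)), 2)
})

test_that("the two-way ANOVA handles degenerate and scaled inputs", {
  outputs <- expand.grid(specimen = c("serum", "saliva"),
                         condition = c("rest", "exercise"),
                         subject = 1:4, stringsAsFactors = FALSE)
  outputs$auc <- 100
  tab <- anova_outputs(outputs)
  expect_identical(tab$statistic[tab$term == "specimen"], 0)
  expect_identical(tab$p_value[tab$term == "specimen"], 1)
  # scale invariance of F and p
  set.seed(10)
  outputs$auc <- rnorm(nrow(outputs), 100, 10) +
    ifelse(outputs$specimen == "serum", 50, 0)
  t1 <- anova_outputs(outputs)
  outputs2 <- outputs; outputs2$auc <- outputs2$auc * 2
  t2 <- anova_outputs(outputs2)
  expect_equal(t1$statistic, t2$statistic, tolerance = 1e-9)
  expect_equal(t1$p_value, t2$p_value, tolerance = 1e-9)
  # missing cells are named
  expect_error(anova_outputs(outputs[outputs$condition == "rest", ]),
               "exercise")
  expect_error(anova_outputs(outputs[-1, ]), "unbalanced")
  tab_i <- anova_outputs(outputs, interaction = TRUE)
  expect_true("specimen:condition" %in% tab_i$term)
})

test_that("the specimen contrast dominates synthetic ground-truth outputs", {
  for (s in c(3L, 8L)) {
    cohort <- generate_cohort(cohort_config(seed = s))
    gt <- Filter(function(p)
      (p$specimen == "serum" & p$scheme == "Q60") |
        (p$specimen == "saliva" & p$scheme == "Q120"), cohort)
    outputs <- do.call(rbind, lapply(gt, total_output))
    tab <- anova_outputs(outputs)
    expect_lt(tab$p_value[tab$term == "specimen"], 0.001)
  }
})
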