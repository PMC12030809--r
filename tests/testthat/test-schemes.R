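test_that("the seven built-in schemes have the canonical grids and caps", {
  expected <- list(
    Q60  = list(n = 25L, max = 6L),
    Q120 = list(n = 13L, max = 6L),
    Q180 = list(n = 9L,  max = 5L),
    Q240 = list(n = 7L,  max = 4L),
    Q360 = list(n = 5L,  max = 3L),
    INT1 = list(n = 6L,  max = 3L),
    INT2 = list(n = 5L,  max = 3L)
  )
  for (nm in names(expected)) {
    s <- build_scheme(nm)
    expect_s3_class(s, "sampling_scheme")
    expect_length(s$grid_hours, expected[[nm]]$n)
    expect_identical(s$max_degree, expected[[nm]]$max)
    expect_lt(s$max_degree, length(s$grid_hours))
    expect_identical(s$grid_hours[1L], 0L)
    expect_identical(s$grid_hours[length(s$grid_hours)], 24L)
    expect_false(is.unsorted(s$grid_hours, strictly = TRUE))
  }
  expect_identical(build_scheme("Q360")$grid_hours,
                   c(0L, 6L, 12L, 18L, 24L))
  expect_identical(build_scheme("INT1")$grid_hours,
                   c(0L, 2L, 4L, 8L, 14L, 24L))
  expect_identical(build_scheme("INT2")$grid_hours,
                   c(0L, 2L, 6L, 16L, 24L))
  expect_error(build_scheme("Q45"), "valid names.*Q60")
})

test_that("specimen scheme lists put ground truth first and restrict saliva", {
  serum <- valid_schemes_for("serum")
  saliva <- valid_schemes_for("saliva")
  expect_length(serum, 7L)
  expect_length(saliva, 5L)
  expect_identical(serum[[1L]]$name, "Q60")
  expect_identical(saliva[[1L]]$name, "Q120")
  saliva_names <- vapply(saliva, `[[`, "", "name")
  expect_false(any(c("Q60", "Q180") %in% saliva_names))
  expect_error(valid_schemes_for("plasma"), "serum, saliva")
  # every alternative grid is a strict subset of its ground truth's
  for (spec in c("serum", "saliva")) {
    schemes <- valid_schemes_for(spec)
    gt <- schemes[[1L]]$grid_hours
    for (s in schemes[-1L]) {
      expect_true(all(s$grid_hours %in% gt))
      expect_lt(length(s$grid_hours), length(gt))
    }
  }
})

test_that("downsample extracts exactly the scheme grid and refuses gaps", {
  set.seed(42)
  prof <- q60_profile(runif(25, 5, 15))
  sub <- downsample(prof, build_scheme("Q120"))
  expect_length(sub$times, 13L)
  expect_identical(sub$times, seq(0, 1440, by = 120))
  expect_identical(sub$values, prof$values[seq(1, 25, by = 2)])
  # identity on the native scheme
  same <- downsample(prof, build_scheme("Q60"))
  expect_identical(same$times, prof$times)
  expect_identical(same$values, prof$values)
  # idempotence
  twice <- downsample(downsample(prof, build_scheme("Q240")),
                      build_scheme("Q240"))
  expect_identical(twice$values, downsample(prof, build_scheme("Q240"))$values)
  # a Q120 saliva profile cannot supply the Q180 grid (hour 3 missing)
  saliva <- cortisol_profile("S01", "rest", "saliva",
                             seq(0, 1440, by = 120), rep(0.5, 13), "Q120")
  expect_error(downsample(saliva, build_scheme("Q180")), "180")
})

test_that("custom schemes load from YAML and built-ins are immutable", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("MY1:", "  hours: [0, 3, 9, 24]", "  max_degree: 2"), path)
  loaded <- load_schemes(path)
  expect_identical(loaded$MY1$grid_hours, c(0L, 3L, 9L, 24L))
  expect_identical(loaded$MY1$max_degree, 2L)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("Q60:", "  hours: [0, 24]", "  max_degree: 1"), bad)
  expect_error(load_schemes(bad), "built-in")

  noend <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("MY2:", "  hours: [0, 3, 9]", "  max_degree: 1"), noend)
  expect_error(load_schemes(noend), "endpoints")
})

test_that("profile construction validates its invariants", {
  expect_error(cortisol_profile("S", "rest", "serum", c(0, 0, 1440),
                                c(1, 2, 3)), "strictly increasing")
  expect_error(cortisol_profile("S", "rest", "serum", c(0, 1500),
                                c(1, 2)), "1440")
  expect_error(cortisol_profile("S", "rest", "serum", c(0, 1440),
                                c(1, -2)), "finite")
  expect_error(cortisol_profile("S", "rest", "serum", c(0, 720, 1440),
                                c(1, 2)), "equal length")
  expect_error(cortisol_profile("S", "sitting", "serum", c(0, 1440),
                                c(1, 2)))
})

test_that("profiles round-trip through the long-format CSV", {
  cohort <- generate_cohort(cohort_config(n_subjects = 2L, seed = 7L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles(cohort, path)
  back <- read_profiles(path)
  expect_length(back, length(cohort))
  key <- function(p) paste(p$subject_id, p$condition, p$specimen)
  back <- back[order(vapply(back, key, ""))]
  orig <- cohort[order(vapply(cohort, key, ""))]
  for (i in seq_along(orig)) {
    expect_identical(back[[i]]$times, orig[[i]]$times)
    expect_equal(back[[i]]$values, orig[[i]]$values)
  }
})
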