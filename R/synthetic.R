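#' Configuration for the synthetic circadian cortisol cohort
#'
#' Parameters of the synthetic generator used in place of clinical data.
#' The deterministic "true" serum concentration is a smooth diurnal
#' template built from zero-mean components over the 24 h window: a
#' day-night contrast term (quadratic shape: high around both 06:00
#' endpoints, nadir in the evening), a morning/evening asymmetry term
#' (cubic shape: raises the morning peak above the pre-waking rise), and
#' a small semidiurnal (12 h) cosine ripple; the exercise condition adds
#' a Gaussian-shaped transient centred on the 10:00 bout. Because every
#' rhythm component integrates to zero over the window, the rest-day
#' 24 h output is exactly `1440 x mesor x subject_effect`.
#'
#' Saliva is an attenuated fraction of serum; in addition its asymmetry
#' and ripple components are damped by `saliva_atten`, reflecting the
#' less complex trends seen in salivary measurements (set
#' `saliva_atten = 1` for exact proportionality). Each channel receives
#' additive zero-mean Gaussian measurement noise and is floored at zero.
#'
#' @param n_subjects Number of subjects (default 8, the study sample
#'   size).
#' @param mesor_serum Serum 24 h mean level, ug/dl (default 7.5; gives
#'   24 h outputs around 10,000-11,500 ug min/dl).
#' @param day_night_amp Amplitude of the day-night contrast term, ug/dl
#'   (default 4; peak-to-nadir swing of 1.5x this value).
#' @param asymmetry_amp Amplitude of the morning/evening asymmetry term,
#'   ug/dl (default 1.8). This term carries the profile's cubic content.
#' @param ripple_amp,ripple_acrophase Semidiurnal cosine amplitude
#'   (default 0.35 ug/dl) and peak time in minutes (default 0); period
#'   720 min.
#' @param exercise_bump_height Height of the exercise transient, ug/dl
#'   (default 2, consistent with 24 h outputs that barely differ
#'   between conditions).
#' @param exercise_bump_center Centre of the transient, minutes since
#'   06:00 (default 240 = 10:00, the exercise bout).
#' @param exercise_bump_width Gaussian sd of the transient, minutes
#'   (default 180: anticipatory rise plus a post-exercise elevation
#'   washing out over a few hours).
#' @param saliva_fraction Saliva/serum concentration ratio (default
#'   0.06).
#' @param saliva_atten Damping of the asymmetry, ripple and exercise
#'   components in saliva (default 0.2; 1 = same shape as serum).
#' @param noise_sd_serum,noise_sd_saliva Additive measurement-noise sd
#'   per channel, ug/dl (defaults 1.2 and 0.06; roughly 15% CV,
#'   covering assay error plus pulsatile scatter about the trend).
#' @param between_subject_sd Log-scale sd of the multiplicative
#'   per-subject effect (default 0.15).
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return A validated `cohort_config` object.
#' @export
cohort_config <- function(n_subjects = 8L, mesor_serum = 7.5,
                          day_night_amp = 4.0, asymmetry_amp = 1.8,
                          ripple_amp = 0.35, ripple_acrophase = 0,
                          exercise_bump_height = 2.0,
                          exercise_bump_center = 240,
                          exercise_bump_width = 180,
                          saliva_fraction = 0.06, saliva_atten = 0.2,
                          noise_sd_serum = 1.2, noise_sd_saliva = 0.06,
                          between_subject_sd = 0.15, seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              mesor_serum = mesor_serum, day_night_amp = day_night_amp,
              asymmetry_amp = asymmetry_amp, ripple_amp = ripple_amp,
              ripple_acrophase = ripple_acrophase,
              exercise_bump_height = exercise_bump_height,
              exercise_bump_center = exercise_bump_center,
              exercise_bump_width = exercise_bump_width,
              saliva_fraction = saliva_fraction,
              saliva_atten = saliva_atten,
              noise_sd_serum = noise_sd_serum,
              noise_sd_saliva = noise_sd_saliva,
              between_subject_sd = between_subject_sd,
              seed = as.integer(seed))
  with(cfg, {
    if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
    if (day_night_amp < 0 || asymmetry_amp < 0 || ripple_amp < 0)
      stop("amplitudes must be >= 0", call. = FALSE)
    if (exercise_bump_height < 0 || exercise_bump_width < 0)
      stop("exercise bump height and width must be >= 0", call. = FALSE)
    if (noise_sd_serum < 0 || noise_sd_saliva < 0 || between_subject_sd < 0)
      stop("noise and between-subject sds must be >= 0", call. = FALSE)
    if (saliva_fraction <= 0 || saliva_fraction >= 1)
      stop("saliva_fraction must lie in (0, 1)", call. = FALSE)
    if (saliva_atten < 0 || saliva_atten > 1)
      stop("saliva_atten must lie in [0, 1]", call. = FALSE)
  })
  structure(cfg, class = "cohort_config")
}

#' Noiseless concentration of the synthetic model
#'
#' Evaluates the deterministic generator curve at time `t`:
#' `subject_effect x [mesor + day_night + asymmetry + ripple]`, plus the
#' Gaussian exercise transient under the exercise condition, floored at
#' zero. With `specimen = "saliva"` the asymmetry, ripple and transient
#' terms are damped by `saliva_atten` and the result is scaled by
#' `saliva_fraction`.
#'
#' @param config A [cohort_config()].
#' @param subject_effect Multiplicative subject effect (1 = population
#'   mean).
#' @param condition `"rest"` or `"exercise"`.
#' @param t Minutes since admission start, within \[0, 1440\];
#'   vectorized.
#' @param specimen `"serum"` (default) or `"saliva"`.
#' @return Concentration(s) in ug/dl.
#' @export
true_concentration <- function(config, subject_effect, condition, t,
                               specimen = c("serum", "saliva")) {
  stopifnot(inherits(config, "cohort_config"))
  condition <- match.arg(condition, c("rest", "exercise"))
  specimen <- match.arg(specimen)
  if (any(t < 0 | t > 1440))
    stop("t must lie within [0, 1440] minutes", call. = FALSE)
  x <- (t - 720) / 720
  day_night <- config$day_night_amp * (3 * x^2 - 1) / 2
  asym <- -config$asymmetry_amp * (5 * x^3 - 3 * x) / 2
  ripple <- config$ripple_amp *
    cos(2 * pi * (t - config$ripple_acrophase) / 720)
  att <- if (specimen == "saliva") config$saliva_atten else 1
  y <- subject_effect *
    (config$mesor_serum + day_night + att * (asym + ripple))
  if (condition == "exercise" && config$exercise_bump_height > 0) {
    y <- y + att * config$exercise_bump_height *
      exp(-(t - config$exercise_bump_center)^2 /
            (2 * config$exercise_bump_width^2))
  }
  if (specimen == "saliva") y <- config$saliva_fraction * y
  pmax(y, 0)
}

#' Generate a synthetic cohort of serum and saliva profiles
#'
#' For every subject and condition, emits a serum profile on the Q60
#' grid (25 points) and a saliva profile on the Q120 grid (13 points).
#' Each channel receives independent zero-mean Gaussian noise (its
#' channel's sd) and is floored at zero. Per-subject effects are drawn
#' once from a log-normal with the configured log-sd. The whole cohort
#' is reproducible from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return List of [cortisol_profile()] objects (`n_subjects x 2
#'   conditions x 2 specimens`), with the config attached as attribute
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  effects <- exp(stats::rnorm(config$n_subjects, 0, config$between_subject_sd))
  t_serum <- scheme_grid_minutes(build_scheme("Q60"))
  t_saliva <- scheme_grid_minutes(build_scheme("Q120"))
  profiles <- vector("list", config$n_subjects * 4L)
  k <- 0L
  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", i)
    for (cond in c("rest", "exercise")) {
      mu_serum <- true_concentration(config, effects[i], cond, t_serum)
      y_serum <- pmax(mu_serum + stats::rnorm(length(t_serum), 0,
                                              config$noise_sd_serum), 0)
      mu_saliva <- true_concentration(config, effects[i], cond, t_saliva,
                                      specimen = "saliva")
      y_saliva <- pmax(mu_saliva + stats::rnorm(length(t_saliva), 0,
                                                config$noise_sd_saliva), 0)
      profiles[[k <- k + 1L]] <- cortisol_profile(sid, cond, "serum",
                                                  t_serum, y_serum, "Q60")
      profiles[[k <- k + 1L]] <- cortisol_profile(sid, cond, "saliva",
                                                  t_saliva, y_saliva, "Q120")
    }
  }
  attr(profiles, "config") <- config
  attr(profiles, "subject_effects") <- effects
  profiles
}

#' Cohort of profiles following a known polynomial truth
#'
#' Fixture generator for parameter-recovery tests: serum-grid (Q60)
#' profiles whose noiseless values follow the given polynomial in scaled
#' time (time affinely mapped from \[0, 1440\] to \[-1, 1\], the basis
#' used by [fit_polynomial()]), perturbed by Gaussian noise and floored
#' at zero.
#'
#' @param coefficients Polynomial coefficients in ascending power of
#'   scaled time; degree (`length - 1`) must be 1-6.
#' @param noise_sd Gaussian noise sd, ug/dl.
#' @param n_subjects Number of profiles to emit (condition `"rest"`).
#' @param seed Integer seed.
#' @return List of [cortisol_profile()] objects.
#' @export
known_polynomial_cohort <- function(coefficients, noise_sd = 0,
                                    n_subjects = 8L, seed = 1L) {
  degree <- length(coefficients) - 1L
  if (degree < 1L || degree > 6L)
    stop("polynomial degree must lie in 1..6", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  t <- scheme_grid_minutes(build_scheme("Q60"))
  x <- (t - 720) / 720
  mu <- drop(outer(x, 0:degree, `^`) %*% coefficients)
  if (any(mu < 0))
    warning("polynomial truth dips below zero; values are floored at 0")
  lapply(seq_len(n_subjects), function(i) {
    y <- pmax(pmax(mu, 0) + stats::rnorm(length(t), 0, noise_sd), 0)
    cortisol_profile(sprintf("S%02d", i), "rest", "serum", t, y, "Q60")
  })
}
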