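#' @title Polynomial validation of cortisol profiles
#' @description
#' Ordinary least-squares polynomial regression of concentration on time,
#' fit per profile across degrees 1 up to the sampling scheme's maximum.
#' Time is affinely scaled from \[0, 1440\] minutes to \[-1, 1\] before
#' fitting so that Vandermonde systems up to degree 6 stay well
#' conditioned; the scaling is stored with the fit and is invisible to
#' predictions.
#' @name polynomial-validation
NULL

.scale_time <- function(t, center = 720, half_range = 720) {
  (t - center) / half_range
}

.vandermonde <- function(x, degree) {
  outer(x, 0:degree, `^`)
}

# R-squared with the zero-variance convention: SS_tot == 0 -> 0, warned
.r_squared <- function(observed, predicted) {
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    warning("reference has zero variance; R^2 reported as 0", call. = FALSE)
    return(0)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

.rmse <- function(observed, predicted) sqrt(mean((observed - predicted)^2))

#' Fit a polynomial of fixed degree to one profile
#'
#' Least-squares polynomial in scaled time. At least `degree + 2` points
#' are required so the fit always retains residual degrees of freedom
#' (never a pure interpolant).
#'
#' @param profile A [cortisol_profile()].
#' @param degree Polynomial degree, 1-6.
#' @return A `poly_fit` object: `degree`, `coefficients` (ascending powers
#'   of scaled time), `scale_params` (centre, half-range in minutes),
#'   `train_times`, `train_values`, `fitted_values`, `residuals`,
#'   `resid_scale` (the unbiased residual standard error
#'   `sqrt(RSS / (n - degree - 1))`, the error scale used by the
#'   stochastic interpolation), `r2_self`, `rmse_self`, `source_scheme`.
#' @examples
#' prof <- known_polynomial_cohort(c(8, 2, -3, 1), noise_sd = 0,
#'                                 n_subjects = 1)[[1]]
#' fit <- fit_polynomial(prof, 3)
#' fit$r2_self  # 1: the truth is exactly representable
#' @export
fit_polynomial <- function(profile, degree) {
  stopifnot(inherits(profile, "cortisol_profile"))
  degree <- as.integer(degree)
  if (degree < 1L || degree > 6L)
    stop("degree must lie in 1..6", call. = FALSE)
  n <- length(profile$times)
  if (degree > n - 2L)
    stop("degree ", degree, " too high for ", n,
         " points (need >= degree + 2 to keep residual degrees of freedom)",
         call. = FALSE)
  x <- .scale_time(profile$times)
  X <- .vandermonde(x, degree)
  fit <- stats::lm.fit(X, profile$values)
  fitted <- drop(X %*% fit$coefficients)
  res <- profile$values - fitted
  structure(
    list(degree = degree,
         resid_scale = sqrt(sum(res^2) / (n - degree - 1L)),
         coefficients = unname(fit$coefficients),
         scale_params = c(center = 720, half_range = 720),
         train_times = profile$times,
         train_values = profile$values,
         fitted_values = fitted,
         residuals = res,
         r2_self = .r_squared(profile$values, fitted),
         rmse_self = .rmse(profile$values, fitted),
         source_scheme = profile$scheme,
         subject_id = profile$subject_id,
         condition = profile$condition,
         specimen = profile$specimen),
    class = "poly_fit"
  )
}

#' @export
print.poly_fit <- function(x, ...) {
  cat(sprintf("<poly_fit degree %d (%s): R^2 = %.4f, RMSE = %.4g ug/dl>\n",
              x$degree, x$source_scheme, x$r2_self, x$rmse_self))
  invisible(x)
}

#' Evaluate a polynomial fit at new times
#'
#' @param object A `poly_fit`.
#' @param times Minutes within \[0, 1440\] (the fitting window; the grids
#'   all span it, so extrapolation is never needed and is refused).
#' @param ... Unused.
#' @return Predicted concentrations in ug/dl.
#' @export
predict.poly_fit <- function(object, times, ...) {
  if (any(times < 0 | times > 1440))
    stop("prediction times must lie within [0, 1440] minutes",
         call. = FALSE)
  x <- .scale_time(times, object$scale_params[["center"]],
                   object$scale_params[["half_range"]])
  drop(.vandermonde(x, object$degree) %*% object$coefficients)
}

#' Fit metrics of a model against a reference profile
#'
#' Computes R^2 and RMSE between the fit's predictions at the reference
#' times and the reference values. With the ground-truth profile as
#' reference this is the "alternative model versus ground-truth data"
#' evaluation surface.
#'
#' @param fit A `poly_fit`.
#' @param reference A [cortisol_profile()] (>= 2 points).
#' @return List with elements `r2` and `rmse`.
#' @export
metrics_against <- function(fit, reference) {
  stopifnot(inherits(fit, "poly_fit"),
            inherits(reference, "cortisol_profile"))
  if (length(reference$times) < 2L)
    stop("reference profile needs at least 2 points", call. = FALSE)
  pred <- predict(fit, reference$times)
  list(r2 = .r_squared(reference$values, pred),
       rmse = .rmse(reference$values, pred))
}

#' Polynomial validation: fit all permitted degrees to one profile
#'
#' Fits degrees 1 through the scheme's maximum, ascending. The profile
#' must lie exactly on the scheme grid.
#'
#' @param profile A [cortisol_profile()] on the scheme's grid.
#' @param scheme The [build_scheme()] the profile was sampled under.
#' @return List of `poly_fit` objects, one per degree, ascending.
#' @export
polynomial_validation <- function(profile, scheme) {
  stopifnot(inherits(profile, "cortisol_profile"),
            inherits(scheme, "sampling_scheme"))
  grid_min <- scheme_grid_minutes(scheme)
  if (!identical(as.numeric(grid_min), as.numeric(profile$times)))
    stop("profile does not lie on the ", scheme$name, " grid", call. = FALSE)
  lapply(seq_len(scheme$max_degree), function(d) fit_polynomial(profile, d))
}

#' Serialize a fit to JSON
#'
#' @param fit A `poly_fit`.
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "poly_fit"))
  payload <- fit[c("degree", "coefficients", "scale_params", "r2_self",
                   "rmse_self", "source_scheme", "subject_id", "condition",
                   "specimen")]
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
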