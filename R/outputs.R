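#' @title 24 h output estimation and equivalence testing
#' @description
#' The clinical summary quantity is the 24 h total cortisol output: the
#' time integral of concentration over the admission window, in
#' ug min/dl. Outputs estimated after stochastic interpolation are
#' compared with the ground-truth estimates by paired two one-sided tests
#' (TOST) of the log-transformed outputs with a region of similarity of
#' +/- 0.25, and ground-truth outputs are compared across specimen and
#' condition by two-way ANOVA.
#' @name outputs-and-equivalence
NULL

#' Estimate 24 h total output from a profile
#'
#' Integrates concentration over the admission window (trapezoidal rule,
#' time in minutes, by default over \[0, 1440\]). The profile must contain
#' both window endpoints.
#'
#' @param x A [cortisol_profile()] or `interpolated_profile`.
#' @param window Integration window in minutes (default `c(0, 1440)`).
#' @param rule `"trapezoid"` (default; ug min/dl), `"trapezoid_hours"`
#'   (same integral with time in hours, ug h/dl) or `"sum"` (simple sum
#'   of concentrations, ug/dl).
#' @return One-row data frame (an output estimate): `subject_id`,
#'   `condition`, `specimen`, `scheme`, `degree`, `source`
#'   (`"observed"`/`"interpolated"`) and `auc`.
#' @examples
#' prof <- cortisol_profile("S01", "rest", "serum",
#'                          times = seq(0, 1440, by = 60),
#'                          values = rep(1, 25))
#' total_output(prof)$auc  # 1440
#' @export
total_output <- function(x, window = c(0, 1440),
                         rule = c("trapezoid", "trapezoid_hours", "sum")) {
  rule <- match.arg(rule)
  if (!inherits(x, c("cortisol_profile", "interpolated_profile")))
    stop("x must be a cortisol_profile or interpolated_profile",
         call. = FALSE)
  keep <- x$times >= window[1L] & x$times <= window[2L]
  times <- x$times[keep]
  values <- x$values[keep]
  if (length(times) < 2L || times[1L] != window[1L] ||
      times[length(times)] != window[2L])
    stop("profile must cover both window endpoints ", window[1L], " and ",
         window[2L], " min", call. = FALSE)
  auc <- switch(rule,
                trapezoid = pracma::trapz(times, values),
                trapezoid_hours = pracma::trapz(times / 60, values),
                sum = sum(values))
  interp <- inherits(x, "interpolated_profile")
  data.frame(
    subject_id = x$subject_id, condition = x$condition, specimen = x$specimen,
    scheme = if (interp) x$source_fit$source_scheme else x$scheme,
    degree = if (interp) x$source_fit$degree else NA_integer_,
    source = if (interp) "interpolated" else "observed",
    auc = auc, stringsAsFactors = FALSE)
}

#' TOST settings
#'
#' @param epsilon Equivalence half-width (default 0.25, on the log-output
#'   scale: roughly +/- 25% ratios).
#' @param alpha One-sided significance level (default 0.05); the reported
#'   CI is the `1 - 2 alpha` (90%) interval, the standard TOST
#'   convention.
#' @param log_transform Compare log outputs (default) or raw differences.
#' @param bounds `"raw"` (default) treats `epsilon` as absolute bounds on
#'   the mean difference; `"smd"` scales the bounds by the sd of the
#'   paired differences (standardized-mean-difference convention).
#' @return A `tost_config` object.
#' @export
tost_config <- function(epsilon = 0.25, alpha = 0.05, log_transform = TRUE,
                        bounds = c("raw", "smd")) {
  bounds <- match.arg(bounds)
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)",
                                     call. = FALSE)
  structure(list(epsilon = epsilon, alpha = alpha,
                 log_transform = isTRUE(log_transform), bounds = bounds),
            class = "tost_config")
}

#' Cohen's d for paired differences
#'
#' Magnitude of the standardized mean difference, `|mean(d)| / sd(d)`.
#'
#' @param d Paired differences (n >= 2, non-degenerate).
#' @return Non-negative effect size.
#' @export
cohens_d_paired <- function(d) {
  if (length(d) < 2L) stop("need at least 2 paired differences",
                           call. = FALSE)
  s <- stats::sd(d)
  if (s == 0) stop("paired differences have zero sd; Cohen's d undefined",
                   call. = FALSE)
  abs(mean(d)) / s
}

#' Paired TOST equivalence test
#'
#' Tests whether paired outputs `y` are equivalent to `x` within a region
#' of similarity of +/- epsilon. With the default log transform the
#' paired differences are `d_i = log(y_i) - log(x_i)`; the two one-sided
#' paired t-tests compare `mean(d)` against `-epsilon` and `+epsilon`
#' with `n - 1` degrees of freedom. Equivalence is declared when both
#' one-sided p-values fall below alpha, which is identical to the
#' `1 - 2 alpha` CI lying strictly inside `(-epsilon, +epsilon)`.
#'
#' @param x,y Positive paired outputs of equal length (n >= 3), e.g.
#'   ground-truth and interpolated 24 h AUCs per subject.
#' @param config A [tost_config()].
#' @return An `equivalence_result`: `estimate` (mean paired difference),
#'   `ci_lower`/`ci_upper`, `p_lower`/`p_upper`, `equivalent`, `cohens_d`,
#'   `epsilon_used`, `n`, `df`.
#' @export
tost_paired <- function(x, y, config = tost_config()) {
  stopifnot(inherits(config, "tost_config"))
  if (length(x) != length(y))
    stop("x and y must be paired (equal length)", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need n >= 3 pairs", call. = FALSE)
  if (config$log_transform) {
    if (any(x <= 0) || any(y <= 0))
      stop("log transform requires strictly positive outputs",
           call. = FALSE)
    d <- log(y) - log(x)
  } else {
    d <- y - x
  }
  m <- mean(d)
  s <- stats::sd(d)
  df <- n - 1L
  eps <- config$epsilon
  if (config$bounds == "smd") {
    if (s == 0)
      stop("zero sd of differences: SMD bounds undefined", call. = FALSE)
    eps <- config$epsilon * s
  }
  if (s == 0) {
    # degenerate: all differences identical; decide by sign alone
    p_lower <- if (m > -eps) 0 else 1
    p_upper <- if (m < eps) 0 else 1
    ci <- c(m, m)
    d_eff <- NA_real_
  } else {
    se <- s / sqrt(n)
    p_lower <- stats::pt((m + eps) / se, df, lower.tail = FALSE)
    p_upper <- stats::pt((m - eps) / se, df, lower.tail = TRUE)
    crit <- stats::qt(1 - config$alpha, df)
    ci <- c(m - crit * se, m + crit * se)
    d_eff <- cohens_d_paired(d)
  }
  structure(
    list(estimate = m, ci_lower = ci[1L], ci_upper = ci[2L],
         p_lower = p_lower, p_upper = p_upper,
         equivalent = max(p_lower, p_upper) < config$alpha,
         cohens_d = d_eff, epsilon_used = eps, alpha = config$alpha,
         log_transform = config$log_transform, n = n, df = df),
    class = "equivalence_result"
  )
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<TOST: estimate %.4f, %d%% CI [%.4f, %.4f], eps %.3g, p = %.3g -> %s",
    ", d = %.3g>\n"),
    x$estimate, round(100 * (1 - 2 * x$alpha)), x$ci_lower, x$ci_upper,
    x$epsilon_used, max(x$p_lower, x$p_upper),
    if (x$equivalent) "equivalent" else "not equivalent", x$cohens_d))
  invisible(x)
}

#' Two-way ANOVA of ground-truth 24 h outputs
#'
#' Fixed-effects ANOVA of output on specimen and condition (main effects
#' by default; `interaction = TRUE` adds specimen:condition). Expects a
#' balanced table of observed ground-truth outputs for both specimens
#' and both conditions.
#'
#' @param outputs Data frame of output estimates (rows from
#'   [total_output()]): columns `specimen`, `condition`, `auc`.
#' @param interaction Include the interaction term (default `FALSE`).
#' @return Data frame with one row per factor: `term`, `df`, `sum_sq`,
#'   `mean_sq`, `statistic` (F), `p_value`.
#' @export
anova_outputs <- function(outputs, interaction = FALSE) {
  need <- c("specimen", "condition", "auc")
  miss <- setdiff(need, names(outputs))
  if (length(miss))
    stop("outputs lack columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab <- table(outputs$specimen, outputs$condition)
  cells <- expand.grid(specimen = c("serum", "saliva"),
                       condition = c("rest", "exercise"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cells))) {
    sp <- cells$specimen[i]; cn <- cells$condition[i]
    if (!(sp %in% rownames(tab)) || !(cn %in% colnames(tab)) ||
        tab[sp, cn] == 0L)
      stop("missing cell: specimen ", sp, ", condition ", cn, call. = FALSE)
  }
  if (length(unique(as.vector(tab[c("serum", "saliva"),
                                  c("rest", "exercise")]))) != 1L)
    stop("unbalanced design: unequal cell counts across specimen x ",
         "condition", call. = FALSE)
  dat <- data.frame(auc = outputs$auc,
                    specimen = factor(outputs$specimen),
                    condition = factor(outputs$condition))
  form <- if (interaction) auc ~ specimen * condition
          else auc ~ specimen + condition
  fit <- stats::aov(form, data = dat)
  s <- summary(fit)[[1L]]
  out <- data.frame(term = trimws(rownames(s)), df = s[["Df"]],
                    sum_sq = s[["Sum Sq"]], mean_sq = s[["Mean Sq"]],
                    statistic = s[["F value"]], p_value = s[["Pr(>F)"]],
                    row.names = NULL, stringsAsFactors = FALSE)
  # fully degenerate data (zero effect and zero residual variance): the
  # 0/0 F ratio is reported as no evidence of an effect
  fix <- which(out$term != "Residuals" & out$sum_sq <= 0 &
                 (is.na(out$statistic) | !is.finite(out$statistic)))
  if (length(fix)) {
    out$statistic[fix] <- 0
    out$p_value[fix] <- 1
  }
  out
}
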