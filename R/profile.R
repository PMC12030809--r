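#' A single 24 h concentration time series
#'
#' One subject x condition x specimen cortisol profile. Times are minutes
#' since the 06:00 admission start (0 to 1440 inclusive), values are
#' concentrations in ug/dl.
#'
#' @param subject_id Opaque subject label.
#' @param condition `"rest"` or `"exercise"`.
#' @param specimen `"serum"` or `"saliva"`.
#' @param times Strictly increasing integer minutes in \[0, 1440\].
#' @param values Finite non-negative concentrations, same length as `times`
#'   (length >= 2).
#' @param scheme Optional name of the sampling scheme the profile lies on.
#' @return A `cortisol_profile` object.
#' @export
cortisol_profile <- function(subject_id, condition, specimen, times, values,
                             scheme = NA_character_) {
  condition <- match.arg(condition, c("rest", "exercise"))
  specimen <- match.arg(specimen, c("serum", "saliva"))
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values) || length(times) < 2L)
    stop("times and values must have equal length >= 2", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(times < 0) || any(times > 1440))
    stop("times must lie within [0, 1440] minutes", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("values must be finite and >= 0", call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id), condition = condition,
         specimen = specimen, times = times, values = values,
         scheme = as.character(scheme)),
    class = "cortisol_profile"
  )
}

#' @export
print.cortisol_profile <- function(x, ...) {
  cat(sprintf("<cortisol_profile %s/%s/%s: %d points%s>\n",
              x$subject_id, x$condition, x$specimen, length(x$times),
              if (!is.na(x$scheme)) paste0(", scheme ", x$scheme) else ""))
  invisible(x)
}

#' @export
length.cortisol_profile <- function(x) length(x$times)

#' @export
as.data.frame.cortisol_profile <- function(x, ...) {
  data.frame(subject_id = x$subject_id, condition = x$condition,
             specimen = x$specimen, time_min = x$times, value = x$values,
             stringsAsFactors = FALSE)
}

#' Convert a list of profiles to a long-format data frame
#'
#' @param profiles List of `cortisol_profile` objects.
#' @return Data frame with columns `subject_id`, `condition`, `specimen`,
#'   `time_min`, `value`.
#' @export
profiles_to_df <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) > 0L)
  do.call(rbind, lapply(profiles, as.data.frame))
}

#' Write profiles to a long-format CSV
#'
#' @param profiles List of `cortisol_profile` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(profiles_to_df(profiles), path, row.names = FALSE)
  invisible(path)
}

#' Read profiles from a long-format CSV
#'
#' Expects columns `subject_id`, `condition`, `specimen`, `time_min`,
#' `value`, one row per measurement; rows are grouped into one profile per
#' subject x condition x specimen.
#'
#' @param path CSV path.
#' @return List of `cortisol_profile` objects.
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "condition", "specimen", "time_min", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("profile CSV lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  keys <- interaction(df$subject_id, df$condition, df$specimen, drop = TRUE)
  out <- lapply(split(df, keys), function(g) {
    g <- g[order(g$time_min), , drop = FALSE]
    cortisol_profile(g$subject_id[1L], g$condition[1L], g$specimen[1L],
                     g$time_min, g$value)
  })
  names(out) <- NULL
  out
}
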