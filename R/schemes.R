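#' @title Canonical 24 h cortisol sampling schemes
#' @description
#' The seven sampling schemes used throughout the package: equidistant
#' down-samplings of the densest clinical grids (Q60 serum, Q120 saliva)
#' plus two intermittent schedules (INT1, INT2) mimicking convenient
#' clinical sampling windows. Each scheme carries the maximum polynomial
#' degree permitted by its degrees of freedom.
#' @name sampling-schemes
NULL

# built-in scheme table: grid in hours since 06:00 admission start
.builtin_schemes <- list(
  Q60  = list(grid_hours = 0:24,                       max_degree = 6L),
  Q120 = list(grid_hours = seq(0L, 24L, by = 2L),      max_degree = 6L),
  Q180 = list(grid_hours = seq(0L, 24L, by = 3L),      max_degree = 5L),
  Q240 = list(grid_hours = seq(0L, 24L, by = 4L),      max_degree = 4L),
  Q360 = list(grid_hours = c(0L, 6L, 12L, 18L, 24L),   max_degree = 3L),
  INT1 = list(grid_hours = c(0L, 2L, 4L, 8L, 14L, 24L), max_degree = 3L),
  INT2 = list(grid_hours = c(0L, 2L, 6L, 16L, 24L),    max_degree = 3L)
)

.specimen_schemes <- list(
  serum  = c("Q60", "Q120", "Q180", "Q240", "Q360", "INT1", "INT2"),
  saliva = c("Q120", "Q240", "Q360", "INT1", "INT2")
)

new_sampling_scheme <- function(name, grid_hours, max_degree) {
  grid_hours <- as.integer(grid_hours)
  max_degree <- as.integer(max_degree)
  stopifnot(length(name) == 1L, is.character(name))
  if (any(grid_hours < 0L) || any(grid_hours > 24L))
    stop("scheme grid must lie within hours 0..24", call. = FALSE)
  if (is.unsorted(grid_hours, strictly = TRUE))
    stop("scheme grid must be strictly increasing", call. = FALSE)
  if (grid_hours[1L] != 0L || grid_hours[length(grid_hours)] != 24L)
    stop("scheme grid must contain both endpoints 0 and 24 h", call. = FALSE)
  if (max_degree < 1L || max_degree >= length(grid_hours))
    stop("max_degree must be positive and below the number of grid points",
         call. = FALSE)
  structure(
    list(name = name, grid_hours = grid_hours, max_degree = max_degree),
    class = "sampling_scheme"
  )
}

#' Build one of the canonical sampling schemes
#'
#' Returns the named scheme with its exact hour grid and the maximum
#' polynomial degree permitted for that grid: Q60 (25 points, degree 6),
#' Q120 (13, 6), Q180 (9, 5), Q240 (7, 4), Q360 (5, 3), INT1
#' (\{0,2,4,8,14,24\} h, degree 3) and INT2 (\{0,2,6,16,24\} h, degree 3).
#'
#' @param name Scheme name, one of `"Q60"`, `"Q120"`, `"Q180"`, `"Q240"`,
#'   `"Q360"`, `"INT1"`, `"INT2"`.
#' @return A `sampling_scheme` object: a list with `name`, `grid_hours`
#'   (strictly increasing integer hours, always including 0 and 24) and
#'   `max_degree`.
#' @examples
#' build_scheme("Q360")
#' length(build_scheme("Q60")$grid_hours)  # 25
#' @seealso [downsample()], [valid_schemes_for()], [load_schemes()]
#' @export
build_scheme <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(.builtin_schemes)) {
    stop("unknown scheme '", paste(name, collapse = ","), "'; valid names: ",
         paste(names(.builtin_schemes), collapse = ", "), call. = FALSE)
  }
  s <- .builtin_schemes[[name]]
  new_sampling_scheme(name, s$grid_hours, s$max_degree)
}

#' Scheme grid in minutes since admission start
#'
#' @param scheme A `sampling_scheme`.
#' @return Integer minutes (hours x 60).
#' @export
scheme_grid_minutes <- function(scheme) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  scheme$grid_hours * 60L
}

#' Sampling schemes valid for a specimen
#'
#' Serum was sampled hourly so every scheme applies; saliva was sampled
#' every two hours, so only schemes whose grids are subsets of the Q120
#' grid apply (Q120, Q240, Q360, INT1, INT2). The first element is always
#' the specimen's ground-truth scheme.
#'
#' @param specimen `"serum"` or `"saliva"`.
#' @return List of `sampling_scheme` objects, ground truth first.
#' @export
valid_schemes_for <- function(specimen) {
  if (!is.character(specimen) || length(specimen) != 1L ||
      !specimen %in% names(.specimen_schemes)) {
    stop("unknown specimen '", paste(specimen, collapse = ","),
         "'; must be one of: serum, saliva", call. = FALSE)
  }
  lapply(.specimen_schemes[[specimen]], build_scheme)
}

#' Ground-truth scheme for a specimen
#'
#' @param specimen `"serum"` or `"saliva"`.
#' @return The densest collected scheme (Q60 for serum, Q120 for saliva).
#' @export
ground_truth_scheme <- function(specimen) {
  valid_schemes_for(specimen)[[1L]]
}

#' Load user-defined sampling schemes from a YAML config file
#'
#' The file maps scheme names to a list with `hours` (sampling times) and
#' `max_degree`, e.g. `MY1: {hours: [0, 3, 9, 24], max_degree: 2}`. The
#' seven built-in schemes are immutable and may not be redefined.
#'
#' @param path Path to a YAML file.
#' @return Named list of `sampling_scheme` objects.
#' @export
load_schemes <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(names(cfg)) || any(!nzchar(names(cfg))))
    stop("scheme config must be a named mapping", call. = FALSE)
  clash <- intersect(names(cfg), names(.builtin_schemes))
  if (length(clash))
    stop("built-in schemes may not be redefined: ",
         paste(clash, collapse = ", "), call. = FALSE)
  out <- lapply(names(cfg), function(nm) {
    entry <- cfg[[nm]]
    if (is.null(entry$hours) || is.null(entry$max_degree))
      stop("scheme '", nm, "' needs fields 'hours' and 'max_degree'",
           call. = FALSE)
    new_sampling_scheme(nm, entry$hours, entry$max_degree)
  })
  names(out) <- names(cfg)
  out
}

#' @export
print.sampling_scheme <- function(x, ...) {
  cat(sprintf("<sampling_scheme %s: %d points, max degree %d>\n",
              x$name, length(x$grid_hours), x$max_degree))
  cat("  hours:", paste(x$grid_hours, collapse = " "), "\n")
  invisible(x)
}

#' Down-sample a profile onto a scheme grid
#'
#' Extracts the sub-profile at exactly the scheme's sampling times
#' (converted to minutes). Every scheme time must be present in the
#' profile: a saliva profile collected at Q120 cannot, for example, be
#' down-sampled to Q180 because hour 3 was never sampled.
#'
#' @param profile A [cortisol_profile()].
#' @param scheme A `sampling_scheme`.
#' @return A `cortisol_profile` restricted to the scheme grid, with a
#'   `scheme` attribute set to the scheme's name.
#' @export
downsample <- function(profile, scheme) {
  stopifnot(inherits(profile, "cortisol_profile"),
            inherits(scheme, "sampling_scheme"))
  grid_min <- scheme_grid_minutes(scheme)
  idx <- match(grid_min, profile$times)
  if (anyNA(idx)) {
    missing <- grid_min[is.na(idx)]
    stop("profile for subject '", profile$subject_id,
         "' lacks scheme ", scheme$name, " times (minutes): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cortisol_profile(
    subject_id = profile$subject_id,
    condition  = profile$condition,
    specimen   = profile$specimen,
    times      = profile$times[idx],
    values     = profile$values[idx],
    scheme     = scheme$name
  )
}
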