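# shared fixtures, all built in code

q60_minutes <- function() seq(0, 1440, by = 60)

# a profile with the given values on the Q60 grid
q60_profile <- function(values, subject = "S01", condition = "rest",
                        specimen = "serum") {
  cortisol_profile(subject, condition, specimen, q60_minutes(), values,
                   scheme = "Q60")
}

# flat profile at a constant concentration
flat_profile <- function(level = 1, ...) {
  q60_profile(rep(level, 25), ...)
}

# independent least-squares oracle: direct normal-equations solve on the
# scaled-time Vandermonde basis
normal_equations_fit <- function(times, values, degree) {
  x <- (times - 720) / 720
  X <- outer(x, 0:degree, `^`)
  drop(solve(crossprod(X), crossprod(X, values)))
}

# independent fine-grid Gaussian-KDE oracle for the density mode
kde_mode_oracle <- function(values, n_grid = 20001L) {
  bw <- stats::bw.nrd0(values)
  grid <- seq(min(values) - 3 * bw, max(values) + 3 * bw,
              length.out = n_grid)
  dens <- vapply(grid, function(g)
    sum(stats::dnorm((g - values) / bw)), numeric(1))
  grid[which.max(dens)]
}
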