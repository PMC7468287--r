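# Small shared fixtures: a 24^3 two-week phantom and quick registration
# parameters, generated once per test run. Sizes are chosen for speed;
# acceptance tests use the package defaults.

quick_params <- function(...) {
  registration_params(levels = 2, iterations = c(60, 30), ...)
}

small_spec <- function(...) {
  phantom_spec(grid_shape = c(24, 24, 24), n_weeks = 2, ...)
}

small_series <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(small_spec())
    cache
  }
})

# 32^3 series for quantitative recovery checks: at 24^3 the fixed-scale
# (4 mm) fissure-convergence term spans a large fraction of the object, so
# net mask growth genuinely falls below the planted radial rate; from 32^3
# up the planted rates dominate.
mid_series <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_phantom(phantom_spec(grid_shape = c(32, 32, 32),
                                              n_weeks = 2))
    cache
  }
})

# a smooth analytic displacement field on a small grid: u(x) = a * x
linear_field <- function(a = 0.1, n = 16, spacing = c(1, 1, 1)) {
  dm <- c(n, n, n)
  vec <- array(0, c(dm, 3))
  for (ax in 1:3) {
    coord <- (slice.index(array(0, dm), ax) - 1) * spacing[ax]
    vec[, , , ax] <- a * coord
  }
  displacement_field(vec, spacing = spacing)
}
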