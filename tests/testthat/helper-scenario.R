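# Shared fixtures, generated in code and cached per test run.
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Small square-celled scenario for fast unit tests.
tiny_config <- function(seed = 42, ...) {
  scenario_config(nrow = 16, ncol = 32, lon_min = 100, lon_max = 116,
                  lat_min = 24, lat_max = 32, decor_length = 5,
                  n_occurrences = 120, seed = seed, ...)
}

tiny_scenario <- function() memo("tiny", generate_scenario(tiny_config()))

# Default study-condition scenario (used by the acceptance suite).
default_scenario <- function() memo("default", generate_scenario(scenario_config()))

# Random monthly climatology series for bioclim oracle tests.
random_monthly <- function(n, seed) {
  withr::with_seed(seed, {
    tmin <- matrix(runif(n * 12, -5, 15), n)
    tmax <- tmin + matrix(runif(n * 12, 0, 15), n)
    prec <- matrix(rexp(n * 12, rate = 1 / 80), n)
    list(tmin = tmin, tmax = tmax, prec = prec)
  })
}

# Wrap a cellwise series into a 1 x n monthly_climatology.
clim_from_series <- function(tmin, tmax, prec) {
  n <- nrow(tmin)
  monthly_climatology(
    tmin = lapply(1:12, function(m) matrix(tmin[, m], n, 1)),
    tmax = lapply(1:12, function(m) matrix(tmax[, m], n, 1)),
    prec = lapply(1:12, function(m) matrix(prec[, m], n, 1)),
    xll = 0, yll = 0, cellsize = 0.5
  )
}

# Small random presence/background value matrices on named variables.
random_instance <- function(n_bg = 100, m = 10, vars = c("a", "b", "c"), seed = 1) {
  withr::with_seed(seed, {
    bg <- matrix(runif(n_bg * length(vars)), n_bg,
                 dimnames = list(NULL, vars))
    pres <- matrix(runif(m * length(vars), 0.2, 0.8), m,
                   dimnames = list(NULL, vars))
    list(pres = pres, bg = bg)
  })
}

# Uniform single-layer suitability stack helper.
suit_stack <- function(vals, xll = 100, yll = 24, cellsize = 0.5) {
  layer_stack(list(suitability = vals), xll, yll, cellsize)
}
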