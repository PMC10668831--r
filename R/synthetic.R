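#' Synthetic study-scenario configuration
#'
#' Defines a fully synthetic study region: a geographic grid, smooth
#' spatially autocorrelated climate fields with deterministic
#' latitudinal/longitudinal/altitudinal structure, a known bivariate
#' Gaussian niche in two informative bioclim variables, pure-noise
#' variables, and future epochs obtained by configured warming offsets
#' and precipitation scaling. The defaults emulate a subtropical
#' monsoon-climate river-basin study window (100-123 degE, 24-35 degN at
#' quarter-degree resolution) with two future scenario tags of low and high
#' radiative forcing, and a niche whose optimum moves north-eastward
#' under warming.
#'
#' @param nrow,ncol Grid height and width in cells.
#' @param lon_min,lon_max,lat_min,lat_max Grid bounds, decimal degrees.
#' @param decor_length Spatial decorrelation length of the smooth random
#'   fields, in cells (Gaussian filter sigma).
#' @param niche_vars Two informative variable names (must be bioclim
#'   layers), default annual mean temperature and annual precipitation.
#' @param niche_optima,niche_breadths Optimum and Gaussian breadth for
#'   each informative variable, in its own units (degrees C, mm).
#' @param n_noise Number of uninformative smooth noise variables.
#' @param noise_decor_length Decorrelation length (cells) of the noise
#'   variables; shorter than the climate fields so they emulate
#'   unrelated environmental layers with their own spatial scale.
#' @param warming Named vector of warming offsets (degrees C) per future
#'   scenario tag.
#' @param prec_scale Named vector (same tags) of precipitation scale
#'   factors.
#' @param n_occurrences Default occurrence count drawn by
#'   [sample_occurrences()].
#' @param seed RNG seed for field generation.
#' @param t_base Mean annual temperature (degrees C) at the reference
#'   point (grid centre, sea level).
#' @param seasonal_amplitude Annual temperature cycle semi-amplitude.
#' @param diurnal_range Mean diurnal temperature range (tmax - tmin).
#' @param lat_gradient,lon_gradient Cooling rate north- and eastward
#'   (degrees C per degree); together they set the direction the niche
#'   shifts under warming.
#' @param lapse_rate Altitudinal cooling, degrees C per km.
#' @param temp_noise_sd,diurnal_noise_sd SDs of the smooth random
#'   components of temperature and diurnal range.
#' @param alt_base,alt_amplitude Altitude field: base level (m) and SD of
#'   its smooth random component.
#' @param prec_base Annual precipitation (mm) at field value zero.
#' @param prec_log_sd Log-scale SD of the smooth precipitation field.
#' @param prec_ne_gradient Log-scale decline of precipitation per degree
#'   along the axis defined by the temperature gradients; makes the
#'   future precipitation-optimal contour move coherently with the
#'   warming-shifted thermal band.
#' @param monsoon_strength Seasonal concentration of precipitation in
#'   \[0, 1).
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(nrow = 44, ncol = 92,
                            lon_min = 100, lon_max = 123,
                            lat_min = 24, lat_max = 35,
                            decor_length = 10,
                            niche_vars = c("bio1", "bio12"),
                            niche_optima = c(17, 1100),
                            niche_breadths = c(1, 120),
                            n_noise = 3,
                            noise_decor_length = 4,
                            warming = c(ssp126 = 1.7, ssp585 = 4.0),
                            prec_scale = c(ssp126 = 1.05, ssp585 = 1.10),
                            n_occurrences = 200,
                            seed = 1,
                            t_base = 17, seasonal_amplitude = 9,
                            diurnal_range = 9,
                            lat_gradient = 0.7, lon_gradient = 0.8,
                            lapse_rate = 5.5,
                            temp_noise_sd = 0.8, diurnal_noise_sd = 1,
                            alt_base = 400, alt_amplitude = 350,
                            prec_base = 1100, prec_log_sd = 0.35,
                            prec_ne_gradient = 0.03,
                            monsoon_strength = 0.9) {
  cfg <- as.list(environment())
  num <- unlist(cfg[vapply(cfg, is.numeric, logical(1))])
  if (any(!is.finite(num))) stop("non-finite values in scenario configuration")
  if (!(lon_min < lon_max && lat_min < lat_max)) stop("grid bounds must be strictly ordered")
  if (decor_length <= 0) stop("decorrelation length must be positive")
  if (any(niche_breadths <= 0)) stop("niche breadths must be positive")
  if (n_occurrences < 1) stop("need at least one occurrence")
  if (length(niche_vars) != 2 || length(niche_optima) != 2 || length(niche_breadths) != 2) {
    stop("exactly two informative niche variables are required")
  }
  if (!identical(sort(names(warming)), sort(names(prec_scale)))) {
    stop("warming and prec_scale must share scenario tags")
  }
  csx <- (lon_max - lon_min) / ncol
  csy <- (lat_max - lat_min) / nrow
  if (abs(csx - csy) > 1e-9) stop("bounds and grid shape must give square cells")
  cfg$cellsize <- csx
  structure(cfg, class = "scenario_config")
}

# Separable Gaussian low-pass filter of a matrix, with row-normalized
# kernels so edges are not attenuated.
gaussian_smooth <- function(x, sigma) {
  kmat <- function(n) {
    d <- outer(seq_len(n), seq_len(n), `-`)
    k <- exp(-d^2 / (2 * sigma^2))
    k / rowSums(k)
  }
  kmat(nrow(x)) %*% x %*% t(kmat(ncol(x)))
}

# Smooth standardized (mean 0, sd 1) random field; degenerates to zeros
# when the filtered noise is constant.
smooth_field <- function(nrow, ncol, sigma) {
  f <- gaussian_smooth(matrix(stats::rnorm(nrow * ncol), nrow, ncol), sigma)
  s <- stats::sd(f)
  if (s < 1e-12) matrix(0, nrow, ncol) else (f - mean(f)) / s
}

#' Generate a synthetic study scenario
#'
#' Builds the altitude field, monthly tmin/tmax/precipitation
#' climatologies for the current epoch and each configured future tag,
#' the noise variables, and the true suitability layer
#' `S = exp(-(v1-mu1)^2 / (2 s1^2)) * exp(-(v2-mu2)^2 / (2 s2^2))`
#' per epoch, where v1 and v2 are the two informative bioclim variables
#' derived from the generated climatologies. Identical configuration and
#' seed give a bit-identical scenario.
#'
#' @param config A [scenario_config()].
#' @return A `synthetic_scenario` list: `config`, `epochs`, `alt`,
#'   `noise`, `clim` (per-epoch [monthly_climatology()]), `truth`
#'   (per-epoch single-layer suitability stacks).
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  nr <- cfg$nrow; nc <- cfg$ncol; cs <- cfg$cellsize

  fields <- withr::with_seed(cfg$seed, {
    list(
      alt = smooth_field(nr, nc, cfg$decor_length),
      temp = smooth_field(nr, nc, cfg$decor_length),
      diurnal = smooth_field(nr, nc, cfg$decor_length),
      prec = smooth_field(nr, nc, cfg$decor_length),
      noise = lapply(seq_len(cfg$n_noise), function(i)
        smooth_field(nr, nc, cfg$noise_decor_length))
    )
  })

  lat <- matrix(rep(cfg$lat_min + (nr - seq_len(nr) + 0.5) * cs, nc), nr)
  lon <- matrix(rep(cfg$lon_min + (seq_len(nc) - 0.5) * cs, each = nr), nr)
  lat_ref <- (cfg$lat_min + cfg$lat_max) / 2
  lon_ref <- (cfg$lon_min + cfg$lon_max) / 2

  alt <- pmax(cfg$alt_base + cfg$alt_amplitude * fields$alt, 0)
  dr <- pmax(cfg$diurnal_range + cfg$diurnal_noise_sd * fields$diurnal, 1)

  w <- 1 + cfg$monsoon_strength * cos(2 * pi * (1:12 - 7) / 12)
  w <- w / sum(w)  # monthly precipitation weights, exact sum 1
  # precipitation declines along the same axis temperature does, so a
  # wetter future moves the precipitation-optimal contour the same way
  # warming moves the thermal band
  gnorm <- sqrt(cfg$lon_gradient^2 + cfg$lat_gradient^2)
  u <- if (gnorm > 0) {
    (cfg$lon_gradient * (lon - lon_ref) + cfg$lat_gradient * (lat - lat_ref)) / gnorm
  } else 0
  prec_annual0 <- cfg$prec_base *
    exp(-cfg$prec_ne_gradient * u + cfg$prec_log_sd * fields$prec)

  epochs <- c("current", names(cfg$warming))
  clim <- list(); truth <- list()
  for (ep in epochs) {
    dT <- if (ep == "current") 0 else cfg$warming[[ep]]
    psc <- if (ep == "current") 1 else cfg$prec_scale[[ep]]
    tmean_annual <- cfg$t_base + dT -
      cfg$lat_gradient * (lat - lat_ref) -
      cfg$lon_gradient * (lon - lon_ref) -
      cfg$lapse_rate * alt / 1000 +
      cfg$temp_noise_sd * fields$temp
    tmin <- list(); tmax <- list(); prec <- list()
    for (m in 1:12) {
      tm <- tmean_annual + cfg$seasonal_amplitude * cos(2 * pi * (m - 7) / 12)
      tmin[[m]] <- tm - dr / 2
      tmax[[m]] <- tm + dr / 2
      prec[[m]] <- prec_annual0 * psc * w[m]
    }
    clim[[ep]] <- monthly_climatology(tmin, tmax, prec,
                                      cfg$lon_min, cfg$lat_min, cs)
    bio <- compute_bioclim(clim[[ep]])
    v1 <- bio$layers[[cfg$niche_vars[1]]]
    v2 <- bio$layers[[cfg$niche_vars[2]]]
    S <- exp(-(v1 - cfg$niche_optima[1])^2 / (2 * cfg$niche_breadths[1]^2)) *
         exp(-(v2 - cfg$niche_optima[2])^2 / (2 * cfg$niche_breadths[2]^2))
    truth[[ep]] <- layer_stack(list(truth = S), cfg$lon_min, cfg$lat_min, cs)
  }

  noise <- fields$noise
  names(noise) <- paste0("noise", seq_along(noise))
  structure(
    list(config = cfg, epochs = epochs, alt = alt, noise = noise,
         clim = clim, truth = truth),
    class = "synthetic_scenario"
  )
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("<synthetic_scenario> %d x %d cells, epochs: %s\n",
              x$config$nrow, x$config$ncol, paste(x$epochs, collapse = ", ")))
  invisible(x)
}

#' Model-ready layer stack for one epoch
#'
#' Derives the 19 bioclim variables from the epoch's monthly climatology
#' and attaches altitude and the noise variables.
#'
#' @param scenario A `synthetic_scenario`.
#' @param epoch Epoch tag (`"current"` or a future tag).
#' @param vars Layers to keep; the default is the study stack of the two
#'   informative variables plus the noise variables.
#' @return A [layer_stack()].
#' @export
scenario_stack <- function(scenario, epoch = "current",
                           vars = c(scenario$config$niche_vars,
                                    names(scenario$noise))) {
  if (!epoch %in% scenario$epochs) stop("unknown epoch: ", epoch)
  bio <- compute_bioclim(scenario$clim[[epoch]])
  layers <- bio$layers
  layers$alt <- scenario$alt
  for (nm in names(scenario$noise)) layers[[nm]] <- scenario$noise[[nm]]
  stk <- layer_stack(layers, bio$xll, bio$yll, bio$cellsize)
  select_layers(stk, vars)
}

#' Sample occurrence records from the true niche
#'
#' Draws `n` distinct grid cells with probability proportional to the
#' true suitability S (without replacement, mirroring downstream
#' one-record-per-cell thinning) and jitters each record uniformly
#' within its cell.
#'
#' @param scenario A `synthetic_scenario`.
#' @param epoch Epoch whose truth layer is sampled.
#' @param n Number of records (default from the configuration).
#' @param seed RNG seed.
#' @param species Species label written on the records.
#' @return An [occurrence_set()].
#' @export
sample_occurrences <- function(scenario, epoch = "current",
                               n = scenario$config$n_occurrences,
                               seed = scenario$config$seed,
                               species = "synthetic_species") {
  if (!epoch %in% scenario$epochs) stop("unknown epoch: ", epoch)
  if (n < 1) stop("n must be at least 1")
  S <- scenario$truth[[epoch]]$layers$truth
  p <- as.vector(S)
  p[is.na(p)] <- 0
  if (sum(p) <= 0) stop("true suitability is zero everywhere; cannot sample")
  if (sum(p > 0) < n) stop("fewer cells with positive suitability than requested records")
  grid <- scenario$truth[[epoch]]
  lats <- cell_lats(grid); lons <- cell_lons(grid)
  cs <- grid$cellsize
  withr::with_seed(seed, {
    cells <- sample(length(p), n, prob = p)
    rows <- ((cells - 1) %% grid$nrow) + 1
    cols <- ((cells - 1) %/% grid$nrow) + 1
    jit_lon <- stats::runif(n, -cs / 2, cs / 2)
    jit_lat <- stats::runif(n, -cs / 2, cs / 2)
    occurrence_set(species,
                   lons[cols] + jit_lon, lats[rows] + jit_lat,
                   source = "synthetic")
  })
}

#' Write a scenario to disk
#'
#' Writes the altitude, noise and monthly climatology layers of each
#' epoch as ESRI ASCII grids under `dir/<epoch>/`.
#'
#' @param scenario A `synthetic_scenario`.
#' @param dir Output directory.
#' @return Invisibly, written paths.
#' @export
write_scenario <- function(scenario, dir) {
  paths <- character(0)
  for (ep in scenario$epochs) {
    stk <- scenario$clim[[ep]]
    sub <- file.path(dir, ep)
    paths <- c(paths, write_asc(stk, sub))
    paths <- c(paths, write_asc(scenario$truth[[ep]], sub))
  }
  base <- layer_stack(c(list(alt = scenario$alt), scenario$noise),
                      scenario$config$lon_min, scenario$config$lat_min,
                      scenario$config$cellsize)
  paths <- c(paths, write_asc(base, dir))
  invisible(paths)
}
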