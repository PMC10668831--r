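#' @keywords internal
"_PACKAGE"

# Mean Earth radius (km) used for all spherical geometry in the package.
EARTH_RADIUS_KM <- 6371

deg2rad <- function(x) x * pi / 180

#' Great-circle (haversine) distance
#'
#' Distance between two points on the sphere of radius 6,371 km.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Distance in kilometres.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dp <- deg2rad(lat2 - lat1); dl <- deg2rad(lon2 - lon1)
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Initial great-circle bearing
#'
#' @inheritParams haversine_km
#' @return Bearing in degrees clockwise from north, in \[0, 360).
#' @export
initial_bearing <- function(lon1, lat1, lon2, lat2) {
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2); dl <- deg2rad(lon2 - lon1)
  y <- sin(dl) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl)
  (atan2(y, x) * 180 / pi) %% 360
}

#' Eight-sector compass label
#'
#' Maps a bearing to one of N, NE, E, SE, S, SW, W, NW using 45-degree
#' sectors centred on the eight compass points.
#'
#' @param bearing Bearing in degrees clockwise from north.
#' @return Character label.
#' @export
compass_label <- function(bearing) {
  sectors <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
  sectors[floor(((bearing + 22.5) %% 360) / 45) + 1]
}

# Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Soft-threshold operator for L1 proximal steps.
soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Derive a per-stage child seed from a global seed
#'
#' Stages are registered by name so that any stage can be re-run in
#' isolation with the same stream it would see inside [run_pipeline()].
#'
#' @param seed Global integer seed.
#' @param stage Stage name (see `names(nichemax:::STAGE_OFFSETS)`).
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  offset <- STAGE_OFFSETS[[stage]]
  if (is.null(offset)) stop("unknown pipeline stage: ", stage)
  as.integer((as.numeric(seed) * 131 + offset) %% .Machine$integer.max)
}

STAGE_OFFSETS <- list(
  scenario = 1L, occurrences = 2L, background = 3L, initial_fit = 4L,
  tuning = 5L, replicates = 6L, jackknife = 7L
)

`%||%` <- function(a, b) if (is.null(a)) b else a
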