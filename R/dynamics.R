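CHANGE_STATES <- c("never", "stable", "expansion", "shrinkage")

#' Binary range-change overlay between two epochs
#'
#' Binarizes both suitability maps at `threshold` (suitable means
#' `P >= threshold`; the default 0.05 treats any of the poor, moderate or
#' high classes as habitat) and overlays them per cell: `never` (suitable
#' in neither epoch), `stable` (both), `expansion` (future only),
#' `shrinkage` (current only).
#'
#' @param current,future Co-registered suitability maps (single-layer
#'   [layer_stack()]s).
#' @param threshold Binarization threshold in (0, 1).
#' @return A `change_map`: layer_stack whose layer `change` codes cells
#'   0 = never, 1 = stable, 2 = expansion, 3 = shrinkage; per-state areas
#'   (10^4 km^2) as attribute `areas`.
#' @export
change_map <- function(current, future, threshold = 0.05) {
  if (!same_grid(current, future)) stop("current and future maps are not co-registered")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  cur <- suitability_layer(current) >= threshold
  fut <- suitability_layer(future) >= threshold
  valid <- current$mask & future$mask
  code <- matrix(NA_real_, current$nrow, current$ncol)
  code[valid] <- 0
  code[valid & cur & fut] <- 1
  code[valid & !cur & fut] <- 2
  code[valid & cur & !fut] <- 3
  out <- layer_stack(list(change = code), current$xll, current$yll, current$cellsize)
  area <- cell_area_matrix(out)
  areas <- vapply(0:3, function(k) sum(area[!is.na(code) & code == k]), numeric(1))
  attr(out, "areas") <- stats::setNames(areas / 1e4, CHANGE_STATES)
  attr(out, "threshold") <- threshold
  class(out) <- c("change_map", class(out))
  out
}

#' Suitable-area centroid
#'
#' Cell-area-weighted mean of the centre coordinates of all cells whose
#' suitability reaches `threshold`.
#'
#' @param map Suitability map (single-layer [layer_stack()]).
#' @param threshold Binarization threshold in (0, 1).
#' @return List with `lat`, `lon` (decimal degrees).
#' @export
centroid <- function(map, threshold = 0.05) {
  suit <- suitability_layer(map) >= threshold
  suit[is.na(suit)] <- FALSE
  if (!any(suit)) stop("no suitable cells at this threshold")
  w <- cell_area_matrix(map)[suit]
  lat <- matrix(rep(cell_lats(map), map$ncol), nrow = map$nrow)[suit]
  lon <- matrix(rep(cell_lons(map), each = map$nrow), nrow = map$nrow)[suit]
  list(lat = sum(w * lat) / sum(w), lon = sum(w * lon) / sum(w))
}

#' Centroid migration vector
#'
#' Haversine distance (R = 6,371 km), initial great-circle bearing and
#' eight-sector compass label from centroid `a` to centroid `b`.
#'
#' @param a,b Centroids (lists with `lat`, `lon`) as from [centroid()].
#' @return A `migration_vector` list: `distance_km`, `bearing_deg`,
#'   `label`.
#' @export
migration <- function(a, b) {
  d <- haversine_km(a$lon, a$lat, b$lon, b$lat)
  bearing <- if (d == 0) 0 else initial_bearing(a$lon, a$lat, b$lon, b$lat)
  structure(
    list(distance_km = d, bearing_deg = bearing, label = compass_label(bearing)),
    class = "migration_vector"
  )
}

#' @export
print.migration_vector <- function(x, ...) {
  cat(sprintf("<migration> %.1f km, bearing %.1f deg (%s)\n",
              x$distance_km, x$bearing_deg, x$label))
  invisible(x)
}

#' Write a centroid track to CSV
#'
#' @param track Data.frame with columns epoch, lat, lon, distance_km,
#'   bearing_deg, label (distance/bearing relative to the previous row).
#' @param path Output CSV path.
#' @export
write_centroid_track <- function(track, path) {
  utils::write.csv(track, path, row.names = FALSE)
  invisible(path)
}
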