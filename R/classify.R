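SUIT_CLASSES <- c("non", "poor", "moderate", "high")

#' Classify continuous suitability into four habitat classes
#'
#' Reclassifies P in \[0,1\] into non / poor / moderate / high habitat
#' using lower-inclusive intervals `[0, t1)`, `[t1, t2)`, `[t2, t3)`,
#' `[t3, 1]` — with the default thresholds (0.05, 0.33, 0.66) these are
#' the conventional no/low/moderate/high-risk classes.
#'
#' @param map Suitability map: a single-layer [layer_stack()] with values
#'   in \[0,1\] (e.g. from [predict.maxent_model()] or
#'   [replicate_fit()]`$mean_map`).
#' @param thresholds Three strictly increasing values in (0, 1).
#' @return A `classified_map`: layer_stack whose layer `class` codes
#'   cells 0 = non, 1 = poor, 2 = moderate, 3 = high; thresholds kept as
#'   attribute.
#' @export
classify <- function(map, thresholds = c(0.05, 0.33, 0.66)) {
  if (length(thresholds) != 3 || any(!is.finite(thresholds)) ||
      any(thresholds <= 0) || any(thresholds >= 1) || any(diff(thresholds) <= 0)) {
    stop("thresholds must be three strictly increasing values in (0, 1)")
  }
  p <- suitability_layer(map)
  cls <- matrix(NA_real_, map$nrow, map$ncol)
  v <- p[map$mask]
  if (any(v < 0 | v > 1)) stop("suitability values outside [0, 1]")
  cls[map$mask] <- findInterval(v, thresholds)  # lower-inclusive bins
  out <- layer_stack(list(class = cls), map$xll, map$yll, map$cellsize)
  attr(out, "thresholds") <- thresholds
  class(out) <- c("classified_map", class(out))
  out
}

# First layer of a suitability stack.
suitability_layer <- function(map) {
  stopifnot(inherits(map, "layer_stack"))
  map$layers[[1]]
}

#' Per-class habitat areas on the sphere
#'
#' Sums spherical cell areas (see [cell_area_km2()]) per suitability
#' class and reports them in 10^4 km^2.
#'
#' @param cmap A `classified_map` from [classify()].
#' @return Named numeric vector (non, poor, moderate, high) of areas in
#'   units of 10^4 km^2.
#' @export
class_areas <- function(cmap) {
  cls <- cmap$layers$class
  area <- cell_area_matrix(cmap)
  out <- vapply(0:3, function(k) {
    sum(area[!is.na(cls) & cls == k])
  }, numeric(1))
  stats::setNames(out / 1e4, SUIT_CLASSES)
}

#' Share of one class within the suitable total
#'
#' Arithmetic used for headline summaries: the percentage of the total
#' suitable area (poor + moderate + high) occupied by one class.
#'
#' @param areas Named vector as returned by [class_areas()], or any named
#'   vector containing `poor`, `moderate`, `high` entries.
#' @param class Class whose share is reported (default `"high"`).
#' @return Percentage in \[0, 100\].
#' @export
suitable_share_pct <- function(areas, class = "high") {
  total <- sum(areas[c("poor", "moderate", "high")])
  100 * unname(areas[class]) / total
}

#' Write a classified map and its area table
#'
#' @param cmap A `classified_map`.
#' @param dir Output directory; writes `class.asc` (integer codes 0-3)
#'   and `class_areas.csv`.
#' @return Invisibly, written paths.
#' @export
write_classified <- function(cmap, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- write_asc(cmap, dir, vars = "class", digits = 1)
  areas <- class_areas(cmap)
  p2 <- file.path(dir, "class_areas.csv")
  utils::write.csv(
    data.frame(class = names(areas), code = 0:3, area_1e4_km2 = as.numeric(areas)),
    p2, row.names = FALSE)
  invisible(c(p1, p2))
}
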