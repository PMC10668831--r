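#' Occurrence record set
#'
#' Presence coordinates with provenance and a thinning flag. Stored as a
#' data.frame with columns `species`, `longitude`, `latitude`, `source`.
#'
#' @param species Character vector (recycled) of species labels.
#' @param longitude,latitude Decimal-degree coordinates.
#' @param source Provenance tag per record (recycled).
#' @return An object of class `occurrence_set`.
#' @export
occurrence_set <- function(species, longitude, latitude, source = "unknown") {
  if (length(longitude) != length(latitude)) {
    stop("longitude and latitude lengths differ")
  }
  if (length(longitude) == 0) stop("empty occurrence set")
  if (any(!is.finite(longitude)) || any(!is.finite(latitude))) {
    stop("non-finite coordinates in occurrence set")
  }
  df <- data.frame(
    species = rep_len(as.character(species), length(longitude)),
    longitude = as.numeric(longitude),
    latitude = as.numeric(latitude),
    source = rep_len(as.character(source), length(longitude)),
    stringsAsFactors = FALSE
  )
  structure(df, class = c("occurrence_set", "data.frame"), thinned = FALSE)
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %d records (%sthinned)\n",
              nrow(x), if (isTRUE(attr(x, "thinned"))) "" else "not "))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' Read occurrences from CSV
#'
#' Expects the MaxEnt "samples" convention: UTF-8 CSV with header
#' `species,longitude,latitude`, coordinates in decimal degrees.
#'
#' @param path CSV file path.
#' @return An [occurrence_set()] with `source` set to the file name.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("species", "longitude", "latitude")
  if (!all(need %in% names(df))) {
    stop("occurrence CSV must have header species,longitude,latitude")
  }
  occurrence_set(df$species, df$longitude, df$latitude, source = basename(path))
}

#' @rdname read_occurrences
#' @param occ An [occurrence_set()].
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ)[c("species", "longitude", "latitude")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Grid-thin occurrence records
#'
#' Reduces an occurrence set to at most one record per grid cell: within
#' each occupied cell the record with the smallest great-circle distance
#' to the cell centre is kept (ties broken by file order). Records falling
#' outside the grid or on nodata cells are dropped with a message.
#'
#' @param occ An [occurrence_set()].
#' @param grid A [layer_stack()] defining cells and nodata mask.
#' @return A thinned [occurrence_set()] (attribute `thinned = TRUE`).
#' @export
thin_to_grid <- function(occ, grid) {
  if (!inherits(occ, "occurrence_set")) stop("`occ` must be an occurrence_set")
  if (nrow(occ) == 0) stop("empty occurrence set")
  rc <- cell_of(grid, occ$longitude, occ$latitude)
  outside <- is.na(rc$row)
  on_nodata <- !outside & !grid$mask[cbind(rc$row, rc$col)]
  drop <- outside | on_nodata
  if (any(drop)) {
    message(sprintf("thin_to_grid: dropped %d record(s) (%d outside grid, %d on nodata cells)",
                    sum(drop), sum(outside), sum(on_nodata)))
  }
  keep_idx <- which(!drop)
  if (length(keep_idx) == 0) stop("no occurrence records remain after validation")

  lats <- cell_lats(grid); lons <- cell_lons(grid)
  d <- haversine_km(occ$longitude[keep_idx], occ$latitude[keep_idx],
                    lons[rc$col[keep_idx]], lats[rc$row[keep_idx]])
  cell_id <- (rc$row[keep_idx] - 1) * grid$ncol + rc$col[keep_idx]
  # order by distance, stable in input order for exact ties; first per cell wins
  ord <- order(cell_id, d, keep_idx)
  sel <- ord[!duplicated(cell_id[ord])]
  sel <- sort(keep_idx[sel])
  out <- occurrence_set(occ$species[sel], occ$longitude[sel],
                        occ$latitude[sel], occ$source[sel])
  attr(out, "thinned") <- TRUE
  out
}
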