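#' Co-registered raster layer stack
#'
#' A `layer_stack` holds named variable layers on one geographic
#' (longitude/latitude, north-up, cell-registered) grid, together with a
#' shared validity mask. Layers are stored as matrices whose first row is
#' the northernmost row, matching ESRI ASCII grid file order. A cell is
#' valid only where every layer is finite.
#'
#' @param layers Named list of numeric matrices with identical dimensions.
#'   `NA` marks nodata.
#' @param xll,yll Longitude/latitude of the lower-left grid corner
#'   (decimal degrees).
#' @param cellsize Cell size in decimal degrees (square cells).
#' @return An object of class `layer_stack`.
#' @export
layer_stack <- function(layers, xll, yll, cellsize) {
  if (!is.list(layers) || length(layers) == 0 || is.null(names(layers)) ||
      any(names(layers) == "")) {
    stop("`layers` must be a non-empty named list of matrices")
  }
  dims <- lapply(layers, dim)
  if (any(vapply(dims, is.null, logical(1))) ||
      !all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all layers must be matrices sharing one grid shape")
  }
  if (!all(is.finite(c(xll, yll, cellsize))) || cellsize <= 0) {
    stop("invalid grid registration")
  }
  layers <- lapply(layers, function(m) {
    m[!is.finite(m)] <- NA_real_
    storage.mode(m) <- "double"
    m
  })
  mask <- Reduce(`&`, lapply(layers, function(m) is.finite(m)))
  structure(
    list(layers = layers, mask = mask,
         nrow = nrow(layers[[1]]), ncol = ncol(layers[[1]]),
         xll = xll, yll = yll, cellsize = cellsize),
    class = "layer_stack"
  )
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf(
    "<layer_stack> %d x %d cells @ %g deg, lon %g..%g, lat %g..%g\n",
    x$nrow, x$ncol, x$cellsize,
    x$xll, x$xll + x$ncol * x$cellsize,
    x$yll, x$yll + x$nrow * x$cellsize))
  cat(sprintf("  %d layers: %s\n", length(x$layers),
              paste(names(x$layers), collapse = ", ")))
  cat(sprintf("  valid cells: %d / %d\n", sum(x$mask), length(x$mask)))
  invisible(x)
}

#' @rdname layer_stack
#' @param x A `layer_stack`.
#' @export
n_layers <- function(x) length(x$layers)

#' Names of the variables in a stack
#' @param x A `layer_stack`.
#' @export
layer_names <- function(x) names(x$layers)

#' Subset or extend a layer stack
#'
#' @param x A `layer_stack`.
#' @param vars Character vector of layer names to keep.
#' @return A new `layer_stack` (mask recomputed).
#' @export
select_layers <- function(x, vars) {
  missing <- setdiff(vars, names(x$layers))
  if (length(missing)) stop("layers not in stack: ", paste(missing, collapse = ", "))
  layer_stack(x$layers[vars], x$xll, x$yll, x$cellsize)
}

#' @rdname select_layers
#' @param name Layer name to add.
#' @param values Matrix of values on the same grid.
#' @export
add_layer <- function(x, name, values) {
  layers <- x$layers
  layers[[name]] <- values
  layer_stack(layers, x$xll, x$yll, x$cellsize)
}

same_grid <- function(a, b, tol = 1e-9) {
  a$nrow == b$nrow && a$ncol == b$ncol &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Cell-centre coordinates
#'
#' @param x A `layer_stack` (or any object with grid fields).
#' @return `cell_lats()`: latitude of each row centre (row 1 = north);
#'   `cell_lons()`: longitude of each column centre.
#' @export
cell_lats <- function(x) x$yll + (x$nrow - seq_len(x$nrow) + 0.5) * x$cellsize

#' @rdname cell_lats
#' @export
cell_lons <- function(x) x$xll + (seq_len(x$ncol) - 0.5) * x$cellsize

#' Map coordinates to grid cells
#'
#' Cell membership uses half-open intervals `[west, east) x [south, north)`
#' so no point belongs to two cells.
#'
#' @param x A `layer_stack`.
#' @param lon,lat Coordinate vectors in decimal degrees.
#' @return A data.frame with columns `row`, `col` (NA outside the grid).
#' @export
cell_of <- function(x, lon, lat) {
  col <- floor((lon - x$xll) / x$cellsize) + 1
  row <- x$nrow - floor((lat - x$yll) / x$cellsize)
  bad <- !is.finite(lon) | !is.finite(lat) |
    col < 1 | col > x$ncol | row < 1 | row > x$nrow
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Spherical cell areas
#'
#' Area of each grid row's cells on the sphere:
#' `R^2 * dlambda * (sin(phi_north) - sin(phi_south))` with R = 6,371 km.
#' Longitude bands of equal width share the same area within a row.
#'
#' @param x A `layer_stack`.
#' @return Numeric vector of per-row cell areas in km^2 (row 1 = north).
#' @export
cell_area_km2 <- function(x) {
  north <- x$yll + (x$nrow - seq_len(x$nrow) + 1) * x$cellsize
  south <- north - x$cellsize
  EARTH_RADIUS_KM^2 * deg2rad(x$cellsize) *
    (sin(deg2rad(north)) - sin(deg2rad(south)))
}

# Matrix of cell areas (km^2), conformable with layers.
cell_area_matrix <- function(x) {
  matrix(rep(cell_area_km2(x), x$ncol), nrow = x$nrow)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file with the standard
#'   ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value header.
#' @return A single-layer `layer_stack`; the layer is named after the file
#'   (basename without extension) unless `name` is given.
#' @param name Optional layer name.
#' @export
read_asc <- function(path, name = NULL) {
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  n_hdr <- 0
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1)
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1
    } else {
      seek(con, pos)
      break
    }
    if (n_hdr >= 6) break
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[k]])) stop("missing ASCII grid header field: ", k)
  }
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(con, what = double(), quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) {
    stop(sprintf("expected %d values, found %d in %s", nr * nc, length(vals), path))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  nm <- name %||% sub("\\.[^.]*$", "", basename(path))
  lay <- list(m); names(lay) <- nm
  layer_stack(lay, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
}

#' Write layers as ESRI ASCII grids
#'
#' @param x A `layer_stack`.
#' @param dir Output directory (created if needed).
#' @param vars Layers to write (default: all).
#' @param nodata Nodata sentinel written to file.
#' @param digits Significant digits used when formatting values.
#' @return Invisibly, the written file paths.
#' @export
write_asc <- function(x, dir, vars = layer_names(x), nodata = -9999,
                      digits = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (v in vars) {
    m <- x$layers[[v]]
    m[is.na(m)] <- nodata
    path <- file.path(dir, paste0(v, ".asc"))
    hdr <- c(
      sprintf("ncols %d", x$ncol),
      sprintf("nrows %d", x$nrow),
      sprintf("xllcorner %.10g", x$xll),
      sprintf("yllcorner %.10g", x$yll),
      sprintf("cellsize %.10g", x$cellsize),
      sprintf("NODATA_value %g", nodata)
    )
    body <- apply(m, 1, function(r) paste(formatC(r, digits = digits, format = "g"),
                                          collapse = " "))
    writeLines(c(hdr, body), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Extract layer values at occurrence coordinates
#'
#' @param x A `layer_stack`.
#' @param lon,lat Coordinates in decimal degrees.
#' @param vars Layers to extract.
#' @return Matrix (points x variables); NA where a point falls outside the
#'   grid or on a nodata cell.
#' @export
extract_values <- function(x, lon, lat, vars = layer_names(x)) {
  rc <- cell_of(x, lon, lat)
  idx <- cbind(rc$row, rc$col)
  out <- sapply(vars, function(v) x$layers[[v]][idx])
  if (is.null(dim(out))) out <- matrix(out, ncol = length(vars),
                                       dimnames = list(NULL, vars))
  out
}
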