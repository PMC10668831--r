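#' Monthly climatology container
#'
#' Twelve co-registered monthly layers each of minimum temperature,
#' maximum temperature (degrees C) and precipitation (mm), the inputs from
#' which the 19 standard bioclimatic variables are derived.
#'
#' @param tmin,tmax,prec Lists of 12 matrices (January..December) on one
#'   grid.
#' @param xll,yll,cellsize Grid registration (decimal degrees).
#' @return An object of class `monthly_climatology`.
#' @export
monthly_climatology <- function(tmin, tmax, prec, xll, yll, cellsize) {
  for (nm in c("tmin", "tmax", "prec")) {
    x <- get(nm)
    if (!is.list(x) || length(x) != 12) stop(nm, " must be a list of 12 monthly layers")
  }
  layers <- c(stats::setNames(tmin, sprintf("tmin%02d", 1:12)),
              stats::setNames(tmax, sprintf("tmax%02d", 1:12)),
              stats::setNames(prec, sprintf("prec%02d", 1:12)))
  stk <- layer_stack(layers, xll, yll, cellsize)
  valid <- stk$mask
  for (m in 1:12) {
    tmn <- stk$layers[[sprintf("tmin%02d", m)]][valid]
    tmx <- stk$layers[[sprintf("tmax%02d", m)]][valid]
    pr <- stk$layers[[sprintf("prec%02d", m)]][valid]
    if (any(tmx < tmn)) stop(sprintf("tmax < tmin in month %d", m))
    if (any(pr < 0)) stop(sprintf("negative precipitation in month %d", m))
  }
  class(stk) <- c("monthly_climatology", class(stk))
  stk
}

# Row-wise population standard deviation of an n x 12 matrix.
row_sd_pop <- function(x) {
  mu <- rowMeans(x)
  sqrt(rowMeans((x - mu)^2))
}

# n x 12 matrix of 3-month wrap-around window aggregates; FUN row-combines
# the three member columns (rowSums or rowMeans of the submatrix).
quarter_windows <- function(x, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  out <- matrix(NA_real_, nrow(x), 12)
  for (s in 1:12) {
    cols <- ((s - 1):(s + 1)) %% 12 + 1
    out[, s] <- if (aggregate == "sum") rowSums(x[, cols, drop = FALSE])
                else rowMeans(x[, cols, drop = FALSE])
  }
  out
}

#' Derive the 19 bioclimatic variables
#'
#' Computes bio1..bio19 from monthly climatologies using the
#' ANUCLIM/WorldClim definitions: monthly mean temperature is
#' `(tmax + tmin) / 2`; quarters are all 12 wrap-around windows of three
#' consecutive months, with ties between windows broken toward the
#' smallest starting month; bio4 is `100 * sd` of monthly mean temperature
#' and bio15 is `100 * sd(prec) / (1 + mean(prec))`, both with the
#' population standard deviation.
#'
#' Units: degrees C for bio1, bio2, bio5..bio11; unitless x100 for bio3 and
#' bio4; mm for bio12..bio14 and bio16..bio19; coefficient of variation
#' (x100) for bio15.
#'
#' @param clim A [monthly_climatology()].
#' @return A `layer_stack` with layers `bio1`..`bio19`.
#' @export
compute_bioclim <- function(clim) {
  if (!inherits(clim, "monthly_climatology")) {
    stop("`clim` must be a monthly_climatology")
  }
  nr <- clim$nrow; nc <- clim$ncol; n <- nr * nc
  get12 <- function(prefix) {
    x <- sapply(1:12, function(m) as.vector(clim$layers[[sprintf("%s%02d", prefix, m)]]))
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    x
  }
  tmin <- get12("tmin"); tmax <- get12("tmax"); prec <- get12("prec")
  tmean <- (tmax + tmin) / 2

  qt <- quarter_windows(tmean, "mean")  # quarterly mean temperature
  qp <- quarter_windows(prec, "sum")    # quarterly precipitation

  # which.max with smallest-start tie-break; all-NA rows yield NA downstream
  first_max <- function(m) max.col(replace(m, is.na(m), -Inf), ties.method = "first")
  wettest <- first_max(qp);  driest <- first_max(-qp)
  warmest <- first_max(qt);  coldest <- first_max(-qt)
  pick <- function(m, s) m[cbind(seq_len(n), s)]

  bio <- vector("list", 19)
  bio[[1]] <- rowMeans(tmean)
  bio[[2]] <- rowMeans(tmax - tmin)
  bio[[5]] <- apply(tmax, 1, max)
  bio[[6]] <- apply(tmin, 1, min)
  bio[[7]] <- bio[[5]] - bio[[6]]
  # zero annual range forces zero diurnal range; define 0/0 as 0
  bio[[3]] <- ifelse(bio[[7]] == 0, 0, 100 * bio[[2]] / bio[[7]])
  bio[[4]] <- 100 * row_sd_pop(tmean)
  bio[[8]] <- pick(qt, wettest)
  bio[[9]] <- pick(qt, driest)
  bio[[10]] <- pick(qt, warmest)
  bio[[11]] <- pick(qt, coldest)
  bio[[12]] <- rowSums(prec)
  bio[[13]] <- apply(prec, 1, max)
  bio[[14]] <- apply(prec, 1, min)
  bio[[15]] <- 100 * row_sd_pop(prec) / (1 + rowMeans(prec))
  bio[[16]] <- pick(qp, wettest)
  bio[[17]] <- pick(qp, driest)
  bio[[18]] <- pick(qp, warmest)
  bio[[19]] <- pick(qp, coldest)

  layers <- stats::setNames(
    lapply(bio, function(v) matrix(v, nr, nc)),
    paste0("bio", 1:19))
  layer_stack(layers, clim$xll, clim$yll, clim$cellsize)
}
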