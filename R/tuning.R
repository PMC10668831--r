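#' All non-empty feature-class subsets
#'
#' @return Character vector of the 31 non-empty subsets of {L,Q,P,T,H},
#'   ordered by subset size then combination order (L, Q, P, T, H, LQ,
#'   LP, ...).
#' @export
fc_grid_all <- function() {
  letters5 <- c("L", "Q", "P", "T", "H")
  unlist(lapply(1:5, function(k) {
    apply(utils::combn(letters5, k), 2, paste, collapse = "")
  }))
}

#' The 29-combination calibration axis
#'
#' The 31 non-empty feature-class subsets minus the standalone product
#' and threshold classes (which are not used alone in MaxEnt practice),
#' giving the 29-entry axis that together with 40 regularization
#' multipliers yields a 1,160-candidate calibration grid.
#'
#' @return Character vector of 29 feature combinations.
#' @export
fc_grid_paper <- function() setdiff(fc_grid_all(), c("P", "T"))

#' Calibration grid definition
#'
#' @param rm Regularization multipliers: positive, strictly increasing
#'   (default 0.1 to 4.0 in steps of 0.1 — 40 values).
#' @param fc Feature combinations (default all 31 non-empty subsets).
#' @return A `tuning_grid` list.
#' @export
tuning_grid <- function(rm = seq(0.1, 4, by = 0.1), fc = fc_grid_all()) {
  if (length(rm) == 0 || length(fc) == 0) stop("empty tuning grid axis")
  if (any(!is.finite(rm)) || any(rm <= 0)) stop("RM values must be positive")
  if (any(diff(rm) <= 0)) stop("RM values must be strictly increasing")
  fc <- vapply(fc, function(x) paste(parse_fc(x), collapse = ""), character(1),
               USE.NAMES = FALSE)
  if (anyDuplicated(fc)) stop("duplicate feature combinations")
  structure(list(rm = rm, fc = fc), class = "tuning_grid")
}

#' Enumerate candidate models
#'
#' Cartesian product of the grid axes in deterministic order:
#' feature-combination major, regularization-multiplier minor.
#'
#' @param grid A [tuning_grid()].
#' @return Data.frame with columns `fc`, `rm` (one row per candidate).
#' @export
candidate_grid <- function(grid) {
  stopifnot(inherits(grid, "tuning_grid"))
  data.frame(
    fc = rep(grid$fc, each = length(grid$rm)),
    rm = rep(grid$rm, times = length(grid$fc)),
    stringsAsFactors = FALSE
  )
}

#' Fit and score all candidate models by AICc
#'
#' Each candidate is fitted on the full (thinned) presence set against a
#' fixed shared background. With raw predictions standardized to sum to
#' one over the training support (background plus presences),
#' `lnL = sum_presences log(raw)`, `k` counts non-zero coefficients and
#' `AICc = 2k - 2 lnL + 2k(k+1)/(n-k-1)` with `n` the presence count.
#' Candidates with `k >= n - 1` are flagged invalid; `delta_aicc` is the
#' gap to the best valid candidate.
#'
#' @param candidates Data.frame from [candidate_grid()].
#' @param pres,bg Presence / background value matrices.
#' @param n_knots,... Passed to [fit_maxent()].
#' @return A `candidate_models` data.frame: fc, rm, k, lnL, AICc,
#'   delta_aicc, valid; fitted models as attribute `models`.
#' @export
score_candidates <- function(candidates, pres, bg, n_knots = 30, ...) {
  n <- nrow(as_value_matrix(pres))
  rows <- vector("list", nrow(candidates))
  models <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    fit <- fit_maxent(pres, bg, classes = candidates$fc[i],
                      rm = candidates$rm[i], n_knots = n_knots, ...)
    k <- sum(fit$lambda != 0)
    lnL <- sum(log(fit$q_support[fit$pres_idx]))
    valid <- k < n - 1
    aicc <- if (valid) 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1) else NA_real_
    rows[[i]] <- data.frame(fc = candidates$fc[i], rm = candidates$rm[i],
                            k = k, lnL = lnL, AICc = aicc, valid = valid,
                            stringsAsFactors = FALSE)
    models[[i]] <- fit
  }
  out <- do.call(rbind, rows)
  if (!any(out$valid)) stop("all candidate models invalid (k >= n - 1); more presences needed")
  out$delta_aicc <- out$AICc - min(out$AICc[out$valid])
  out$delta_aicc[!out$valid] <- NA_real_
  attr(out, "models") <- models
  class(out) <- c("candidate_models", "data.frame")
  out
}

#' AICc from its components
#'
#' Small-sample corrected Akaike information criterion
#' `2k - 2 lnL + 2k(k+1)/(n-k-1)`.
#'
#' @param k Number of (non-zero) parameters.
#' @param lnL Log-likelihood.
#' @param n Sample size (presence count).
#' @return AICc value; NA when `n - k - 1 <= 0`.
#' @export
aicc <- function(k, lnL, n) {
  ifelse(n - k - 1 > 0, 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1), NA_real_)
}

#' Select the optimal candidate
#'
#' Returns the `delta_aicc = 0` candidate; ties are broken by smaller
#' `k`, then smaller `rm`, then candidate (feature-combination) order.
#'
#' @param scored A `candidate_models` data.frame.
#' @return One-row data.frame of the winning candidate (column `index`
#'   gives its row in `scored`).
#' @export
select_best <- function(scored) {
  valid <- which(scored$valid)
  if (length(valid) == 0) stop("no valid candidates")
  ord <- valid[order(scored$delta_aicc[valid], scored$k[valid],
                     scored$rm[valid], valid)]
  best <- scored[ord[1], , drop = FALSE]
  best$index <- ord[1]
  best
}

#' Replicated final model with subsample train/test splits
#'
#' Fits the selected candidate `reps` times, each on a fresh seeded
#' random train/test split of the presences (subsample replication),
#' evaluates every replicate (AUC, TSS) and averages the cloglog
#' suitability maps cellwise.
#'
#' @param stack A [layer_stack()] providing the model variables for map
#'   prediction.
#' @param pres,bg Presence / background value matrices.
#' @param fc,rm The selected feature combination and regularization
#'   multiplier.
#' @param reps Replicate count (default 10).
#' @param test_percent Percentage of presences held out per replicate
#'   (default 25; must leave both splits non-empty).
#' @param seed Base seed; replicate i uses `seed + i`.
#' @param n_knots,... Passed to [fit_maxent()].
#' @return A `replicate_result` list: `mean_map` (suitability
#'   `layer_stack`), `maps`, `models`, `reports`, `summary`.
#' @export
replicate_fit <- function(stack, pres, bg, fc, rm, reps = 10,
                          test_percent = 25, seed = 1, n_knots = 30, ...) {
  if (test_percent <= 0 || test_percent >= 100) stop("test_percent must be in (0, 100)")
  if (reps < 1) stop("need at least one replicate")
  Xp <- as_value_matrix(pres)
  m <- nrow(Xp)
  n_test <- round(m * test_percent / 100)
  if (n_test < 1 || n_test >= m) stop("test split empty or exhaustive at this presence count")

  maps <- vector("list", reps); models <- vector("list", reps)
  reports <- vector("list", reps)
  for (i in seq_len(reps)) {
    test_idx <- withr::with_seed(seed + i, sample.int(m, n_test))
    train <- Xp[-test_idx, , drop = FALSE]
    test <- Xp[test_idx, , drop = FALSE]
    fit <- fit_maxent(train, bg, classes = fc, rm = rm, n_knots = n_knots, ...)
    models[[i]] <- fit
    reports[[i]] <- evaluate_model(fit, train, bg, test)
    maps[[i]] <- predict(fit, stack, transform = "cloglog")
  }
  mean_vals <- Reduce(`+`, lapply(maps, function(m) {
    v <- m$layers$suitability; v[is.na(v)] <- 0; v
  })) / reps
  mean_vals[!stack$mask] <- NA_real_
  mean_map <- layer_stack(list(suitability = mean_vals),
                          stack$xll, stack$yll, stack$cellsize)
  structure(
    list(mean_map = mean_map, maps = maps, models = models,
         reports = reports, summary = summarize_evals(reports),
         fc = fc, rm = rm, reps = reps, test_percent = test_percent,
         seed = seed),
    class = "replicate_result"
  )
}
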