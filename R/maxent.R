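#' Fit a regularized maximum-entropy presence-background model
#'
#' Maximizes the L1-penalized presence log-likelihood
#' `mean_presence(lambda . f) - log Z - sum_j beta_j |lambda_j|`
#' over the Gibbs density `q(x) = exp(lambda . f(x)) / Z` defined on the
#' background, by cyclic coordinate descent with soft-thresholding and
#' backtracking (the penalized objective never decreases). Presence
#' points are appended to the background support so the normalized
#' likelihood used downstream for AICc is finite.
#'
#' Per-feature penalties are `beta_j = rm * beta_class(m) * s_j`, where
#' `s_j` is the feature's standard deviation over the presence points and
#' `beta_class(m)` follows the published MaxEnt default tables
#' (linear/quadratic/product interpolated on presence count `m`; hinge
#' 0.5; threshold 1.0).
#'
#' @param pres Presence variable values: matrix with named columns (or a
#'   single-point data.frame); one row per presence.
#' @param bg Background variable values (matrix with the same columns) —
#'   typically from [background_sample()].
#' @param features A `feature_spec` from [build_features()]; built from
#'   `bg` with classes `classes` when omitted.
#' @param classes Feature classes used when `features` is NULL.
#' @param rm Regularization multiplier (> 0).
#' @param n_knots Knots per variable for threshold/hinge features.
#' @param max_sweeps,tol Convergence controls: stop when the relative
#'   objective change over a full sweep falls below `tol` (default 1e-6)
#'   or after `max_sweeps` (default 500) sweeps.
#' @param trace Keep the per-feature objective-credit trace needed by
#'   [percent_contribution()] (default TRUE).
#' @return A `maxent_model` object.
#' @export
fit_maxent <- function(pres, bg, features = NULL, classes = "LQ", rm = 1,
                       n_knots = 30, max_sweeps = 500, tol = 1e-6,
                       trace = TRUE) {
  Xp <- as_value_matrix(pres)
  Xb <- as_value_matrix(bg, vars = colnames(Xp))
  m <- nrow(Xp)
  if (m <= 1) stop("need at least 2 presence points")
  if (nrow(Xb) < m) stop("background must be at least as large as the presence set")
  if (!is.finite(rm) || rm <= 0) stop("`rm` must be a positive number")
  if (is.null(features)) features <- build_features(Xb, classes, n_knots)

  Fb <- evaluate_features(features, Xb)
  Fp <- evaluate_features(features, Xp)
  F <- rbind(Fb, Fp)                    # background union presence support
  pres_idx <- nrow(Xb) + seq_len(m)
  N <- nrow(F)
  J <- ncol(F)

  fbar <- colMeans(Fp)
  s <- apply(Fp, 2, stats::sd)
  beta_cls <- vapply(features$class, beta_class_value, numeric(1), m = m)
  beta <- unname(rm * beta_cls * s)

  lambda <- numeric(J)
  eta <- numeric(N)
  logZ <- log(N)
  q <- rep(1 / N, N)
  penalty <- 0
  obj <- mean(eta[pres_idx]) - logZ - penalty
  credit <- numeric(J)

  objective_at <- function(eta, lambda) {
    lz <- logsumexp(eta)
    list(obj = mean(eta[pres_idx]) - lz - sum(beta * abs(lambda)), logZ = lz)
  }

  sweeps <- 0L
  converged <- FALSE
  repeat {
    sweeps <- sweeps + 1L
    obj_sweep_start <- obj
    Eq <- as.vector(crossprod(q, F))
    active <- which(lambda != 0 | abs(fbar - Eq) > beta + 1e-12)
    for (j in active) {
      fj <- F[, j]
      qf <- q * fj
      Ef <- sum(qf)
      h <- sum(qf * fj) - Ef^2
      if (h < 1e-12) next
      g <- fbar[j] - Ef
      lam_new <- soft_threshold(lambda[j] + g / h, beta[j] / h)
      delta <- lam_new - lambda[j]
      if (delta == 0) next
      # backtrack to guarantee a non-decreasing penalized objective
      repeat {
        lam_try <- lambda[j] + delta
        eta_try <- eta + delta * fj
        cand <- objective_at(eta_try, replace(lambda, j, lam_try))
        if (cand$obj >= obj - 1e-12) {
          credit[j] <- credit[j] + (cand$obj - obj)
          obj <- cand$obj
          eta <- eta_try
          logZ <- cand$logZ
          lambda[j] <- lam_try
          q <- exp(eta - logZ)
          break
        }
        delta <- delta / 2
        if (abs(delta) < 1e-14) break
      }
    }
    rel <- abs(obj - obj_sweep_start) / (abs(obj_sweep_start) + 1e-10)
    if (rel < tol) { converged <- TRUE; break }
    if (sweeps >= max_sweeps) break
  }

  entropy <- -sum(ifelse(q > 0, q * log(q), 0))
  structure(
    list(
      features = features, lambda = lambda, beta = beta, rm = rm,
      vars = colnames(Xp), m = m, n_bg = nrow(Xb), n_support = N,
      fbar = fbar, logZ = logZ, entropy = entropy,
      transform = "cloglog",
      objective = obj, gain = obj + log(N),
      converged = converged, sweeps = sweeps,
      trace = if (trace) credit else NULL,
      q_support = q, pres_idx = pres_idx
    ),
    class = "maxent_model"
  )
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> %d features (%s), rm=%g, m=%d presences, %d background\n",
    length(x$lambda), paste(attr(x$features, "classes"), collapse = ""),
    x$rm, x$m, x$n_bg))
  cat(sprintf("  non-zero coefficients: %d; regularized gain: %.4f; %s after %d sweeps\n",
              sum(x$lambda != 0), x$gain,
              if (x$converged) "converged" else "not converged", x$sweeps))
  invisible(x)
}

#' Predict suitability from a fitted model
#'
#' Raw output is the Gibbs density `q(x) = exp(lambda . f(x)) / Z` with
#' the training normalizer Z, so raw values over the training support sum
#' to one. The logistic transform is `c q / (1 + c q)` and the
#' complementary log-log transform `1 - exp(-c q)`, both with
#' `c = exp(H)`, the entropy of the fitted distribution. cloglog is the
#' default, the convention of MaxEnt releases 3.4 and later.
#'
#' @param object A `maxent_model`.
#' @param newdata Matrix of raw variable values (named columns) or a
#'   [layer_stack()].
#' @param transform One of `"cloglog"`, `"logistic"`, `"raw"`.
#' @param ... Unused.
#' @return If `newdata` is a matrix, a numeric vector. If a
#'   `layer_stack`, a single-layer stack named `suitability` (a
#'   suitability map, NA outside the mask).
#' @export
predict.maxent_model <- function(object, newdata,
                                 transform = c("cloglog", "logistic", "raw"),
                                 ...) {
  transform <- match.arg(transform)
  is_stack <- inherits(newdata, "layer_stack")
  X <- as_value_matrix(newdata, vars = object$vars)
  Fx <- evaluate_features(object$features, X)
  raw <- exp(as.vector(Fx %*% object$lambda) - object$logZ)
  out <- switch(transform,
    raw = raw,
    logistic = { c0 <- exp(object$entropy); c0 * raw / (1 + c0 * raw) },
    cloglog = 1 - exp(-exp(object$entropy) * raw))
  if (!is_stack) return(out)
  vals <- matrix(NA_real_, newdata$nrow, newdata$ncol)
  vals[newdata$mask] <- out
  layer_stack(list(suitability = vals), newdata$xll, newdata$yll, newdata$cellsize)
}

#' Per-variable percent contributions
#'
#' Credits each coordinate-descent update's change in the penalized
#' objective to the updated feature's source variable(s) — split equally
#' between the two variables of a product feature — then normalizes the
#' positive per-variable credits to sum to 100.
#'
#' @param model A `maxent_model` fitted with `trace = TRUE`.
#' @return Named numeric vector of percent contributions (attribute
#'   `all_zero` is TRUE when the model has no positive credit, e.g. all
#'   coefficients are zero).
#' @export
percent_contribution <- function(model) {
  if (is.null(model$trace)) stop("model was fitted without a trace; refit with trace = TRUE")
  contrib <- stats::setNames(numeric(length(model$vars)), model$vars)
  f <- model$features
  for (j in seq_along(model$trace)) {
    cr <- model$trace[j]
    if (cr == 0) next
    if (!is.na(f$var2[j])) {
      contrib[f$var1[j]] <- contrib[f$var1[j]] + cr / 2
      contrib[f$var2[j]] <- contrib[f$var2[j]] + cr / 2
    } else {
      contrib[f$var1[j]] <- contrib[f$var1[j]] + cr
    }
  }
  contrib[contrib < 0] <- 0
  total <- sum(contrib)
  if (total <= 0) {
    attr(contrib, "all_zero") <- TRUE
    return(contrib)
  }
  out <- 100 * contrib / total
  attr(out, "all_zero") <- FALSE
  out
}

#' Jackknife variable importance
#'
#' Refits the model with only, and without, each variable in turn and
#' reports regularized training gain, test gain and AUC for each fit,
#' alongside the full-model baselines. Test gain is the mean log raw
#' prediction at test presences plus `log N` of the training support.
#'
#' @param pres,bg Training presence / background value matrices.
#' @param test Optional test-presence value matrix (same columns).
#' @param classes,rm,n_knots Passed to [fit_maxent()].
#' @param ... Further arguments to [fit_maxent()].
#' @return A `jackknife_report`: data.frame with columns `variable`,
#'   `mode` ("with_only"/"without"), `train_gain`, `test_gain`, `auc`,
#'   plus attribute `full` holding the full-model baseline row.
#' @export
jackknife_importance <- function(pres, bg, test = NULL, classes = "LQ",
                                 rm = 1, n_knots = 30, ...) {
  Xp <- as_value_matrix(pres); Xb <- as_value_matrix(bg, vars = colnames(Xp))
  vars <- colnames(Xp)
  if (length(vars) < 2) stop("jackknife needs at least 2 variables")
  Xt <- if (!is.null(test)) as_value_matrix(test, vars = vars)

  measure <- function(v_use) {
    fit <- fit_maxent(Xp[, v_use, drop = FALSE], Xb[, v_use, drop = FALSE],
                      classes = classes, rm = rm, n_knots = n_knots, ...)
    sc_p <- predict(fit, Xp[, v_use, drop = FALSE], transform = "raw")
    sc_b <- predict(fit, Xb[, v_use, drop = FALSE], transform = "raw")
    test_gain <- if (!is.null(Xt)) {
      mean(log(predict(fit, Xt[, v_use, drop = FALSE], transform = "raw"))) +
        log(fit$n_support)
    } else NA_real_
    c(train_gain = fit$gain, test_gain = test_gain, auc = auc(sc_p, sc_b))
  }

  full <- measure(vars)
  rows <- list()
  for (v in vars) {
    with_only <- tryCatch(measure(v), error = function(e) {
      warning("jackknife with-only fit failed for ", v, ": ", conditionMessage(e))
      c(train_gain = NA_real_, test_gain = NA_real_, auc = NA_real_)
    })
    without <- tryCatch(measure(setdiff(vars, v)), error = function(e) {
      warning("jackknife without fit failed for ", v, ": ", conditionMessage(e))
      c(train_gain = NA_real_, test_gain = NA_real_, auc = NA_real_)
    })
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, mode = c("with_only", "without"),
      rbind(with_only, without), row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "full") <- full
  class(out) <- c("jackknife_report", "data.frame")
  out
}

#' Draw a background sample from a stack
#'
#' All valid cells are used when there are at most `n_max`; otherwise a
#' seeded uniform sample of `n_max` cells is drawn (10,000 by default,
#' the MaxEnt convention).
#'
#' @param stack A [layer_stack()].
#' @param n_max Maximum number of background cells.
#' @param seed Integer seed used only when subsampling.
#' @param vars Variables to extract.
#' @return List with `X` (value matrix) and `cells` (data.frame row/col).
#' @export
background_sample <- function(stack, n_max = 10000, seed = 1,
                              vars = layer_names(stack)) {
  valid <- which(stack$mask)
  if (length(valid) > n_max) {
    valid <- withr::with_seed(seed, sample(valid, n_max))
    valid <- sort(valid)
  }
  rows <- ((valid - 1) %% stack$nrow) + 1
  cols <- ((valid - 1) %/% stack$nrow) + 1
  X <- sapply(vars, function(v) stack$layers[[v]][valid])
  if (is.null(dim(X))) X <- matrix(X, ncol = length(vars), dimnames = list(NULL, vars))
  list(X = X, cells = data.frame(row = rows, col = cols))
}

#' Variable values at occurrence points
#'
#' @param stack A [layer_stack()].
#' @param occ An [occurrence_set()].
#' @param vars Variables to extract.
#' @return Value matrix (records x variables); errors if any record sits
#'   on a nodata cell or outside the grid.
#' @export
presence_values <- function(stack, occ, vars = layer_names(stack)) {
  X <- extract_values(stack, occ$longitude, occ$latitude, vars)
  if (any(!is.finite(X))) stop("occurrence record(s) on nodata cells; thin/validate first")
  X
}
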