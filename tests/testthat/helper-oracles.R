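# Independent oracles shared by the unit and acceptance suites.

# Generic convex-solver oracle for the penalized maxent likelihood:
# box-constrained quasi-Newton on the split parameterization
# lambda = a - b with a, b >= 0 (the L1 term becomes smooth).
oracle_objective <- function(pres, bg, features, rm) {
  Fb <- evaluate_features(features, bg)
  Fp <- evaluate_features(features, pres)
  F <- rbind(Fb, Fp)
  pres_idx <- nrow(Fb) + seq_len(nrow(Fp))
  m <- nrow(Fp)
  fbar <- colMeans(Fp)
  s <- apply(Fp, 2, sd)
  beta_cls <- vapply(features$class, nichemax:::beta_class_value, numeric(1), m = m)
  beta <- rm * beta_cls * s
  J <- ncol(F)
  negobj <- function(ab) {
    lam <- ab[1:J] - ab[J + 1:J]
    eta <- as.vector(F %*% lam)
    M <- max(eta)
    -(mean(eta[pres_idx]) - (M + log(sum(exp(eta - M)))) -
        sum(beta * (ab[1:J] + ab[J + 1:J])))
  }
  fit <- optim(rep(0, 2 * J), negobj, method = "L-BFGS-B",
               lower = 0, upper = Inf,
               control = list(maxit = 2000, factr = 10))
  -fit$value
}

# Exhaustive 12-window brute-force oracle for one cell's monthly series.
bioclim_oracle <- function(tmin, tmax, prec) {
  tmean <- (tmax + tmin) / 2
  windows <- lapply(1:12, function(s) ((s - 1):(s + 1)) %% 12 + 1)
  qt <- sapply(windows, function(w) mean(tmean[w]))
  qp <- sapply(windows, function(w) sum(prec[w]))
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  wettest <- which.max(qp); driest <- which.min(qp)
  warmest <- which.max(qt); coldest <- which.min(qt)
  b5 <- max(tmax); b6 <- min(tmin); b7 <- b5 - b6; b2 <- mean(tmax - tmin)
  c(bio1 = mean(tmean), bio2 = b2,
    bio3 = if (b7 == 0) 0 else 100 * b2 / b7,
    bio4 = 100 * sd_pop(tmean), bio5 = b5, bio6 = b6, bio7 = b7,
    bio8 = qt[wettest], bio9 = qt[driest], bio10 = qt[warmest],
    bio11 = qt[coldest], bio12 = sum(prec), bio13 = max(prec),
    bio14 = min(prec), bio15 = 100 * sd_pop(prec) / (1 + mean(prec)),
    bio16 = qp[wettest], bio17 = qp[driest], bio18 = qp[warmest],
    bio19 = qp[coldest])
}
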