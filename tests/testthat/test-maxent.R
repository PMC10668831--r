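test_that("constant features give the uniform maximum-entropy solution", {
  inst <- random_instance(n_bg = 40, m = 5, vars = "x", seed = 3)
  inst$bg[, "x"] <- 2.5   # constant everywhere
  inst$pres[, "x"] <- 2.5
  fit <- fit_maxent(inst$pres, inst$bg, classes = "LQ", rm = 1)
  expect_equal(fit$lambda, rep(0, length(fit$lambda)))
  expect_equal(fit$q_support, rep(1 / fit$n_support, fit$n_support))
  expect_equal(predict(fit, inst$bg, transform = "cloglog"),
               rep(1 - exp(-1), 40), tolerance = 1e-12)
})

test_that("the KKT moment-matching bound holds for every feature", {
  for (seed in 1:3) {
    inst <- random_instance(n_bg = 100, m = 15, seed = seed)
    fit <- fit_maxent(inst$pres, inst$bg, classes = "L", rm = 1,
                      tol = 1e-10, max_sweeps = 2000)
    Fb <- evaluate_features(fit$features, inst$bg)
    Fp <- evaluate_features(fit$features, inst$pres)
    Emod <- as.vector(crossprod(fit$q_support, rbind(Fb, Fp)))
    gap <- abs(colMeans(Fp) - Emod)
    expect_true(all(gap <= fit$beta + 1e-6),
                label = sprintf("seed %d: max violation %.2e", seed,
                                max(gap - fit$beta)))
  }
})

test_that("the fitted objective matches a generic convex-solver oracle", {
  for (seed in 1:3) {
    inst <- random_instance(n_bg = 50, m = 10, seed = seed + 10)
    features <- build_features(inst$bg, "L")
    fit <- fit_maxent(inst$pres, inst$bg, features = features, rm = 1,
                      tol = 1e-12, max_sweeps = 5000)
    expect_equal(fit$objective,
                 oracle_objective(inst$pres, inst$bg, features, rm = 1),
                 tolerance = 1e-5)
  }
})

test_that("raw predictions over the training support sum to one", {
  inst <- random_instance(n_bg = 80, m = 12, seed = 21)
  for (fc in c("L", "LQ", "LQH")) {
    fit <- fit_maxent(inst$pres, inst$bg, classes = fc, rm = 1, n_knots = 8)
    expect_equal(sum(fit$q_support), 1, tolerance = 1e-10, label = fc)
    sc <- predict(fit, rbind(inst$bg, inst$pres), transform = "raw")
    expect_equal(sum(sc), 1, tolerance = 1e-10, label = fc)
  }
})

test_that("increasing the regularization multiplier never densifies the model", {
  inst <- random_instance(n_bg = 150, m = 25, seed = 5)
  k <- sapply(c(0.25, 0.5, 1, 2, 4, 8), function(rm) {
    sum(fit_maxent(inst$pres, inst$bg, classes = "LQ", rm = rm)$lambda != 0)
  })
  expect_true(all(diff(k) <= 0))
})

test_that("cloglog is a monotone transform of raw: rankings agree", {
  sc <- tiny_scenario()
  stk <- scenario_stack(sc, "current")
  occ <- thin_to_grid(sample_occurrences(sc, n = 80, seed = 2), stk)
  bg <- background_sample(stk, seed = 1)
  fit <- fit_maxent(presence_values(stk, occ), bg$X, classes = "LQ", rm = 1)
  raw <- predict(fit, bg$X, transform = "raw")
  clog <- predict(fit, bg$X, transform = "cloglog")
  logi <- predict(fit, bg$X, transform = "logistic")
  expect_identical(order(raw), order(clog))
  expect_identical(order(raw), order(logi))
  expect_true(all(clog >= 0 & clog <= 1))
  expect_true(all(logi >= 0 & logi <= 1))
})

test_that("percent contributions identify the informative variable and sum to 100", {
  hits <- sapply(1:10, function(seed) {
    withr::with_seed(seed, {
      n <- 300
      bg <- cbind(sig = runif(n), n1 = runif(n), n2 = runif(n), n3 = runif(n))
      # presences concentrated at high values of `sig` only
      pres <- cbind(sig = runif(40, 0.7, 1), n1 = runif(40),
                    n2 = runif(40), n3 = runif(40))
    })
    fit <- fit_maxent(pres, bg, classes = "LQ", rm = 1)
    pc <- percent_contribution(fit)
    expect_equal(sum(pc), 100, tolerance = 1e-6)
    pc["sig"] > max(pc[c("n1", "n2", "n3")])
  })
  expect_gte(sum(hits), 8)
})

test_that("zero-coefficient models report an explicit all-zero contribution", {
  inst <- random_instance(n_bg = 40, m = 5, vars = "x", seed = 3)
  inst$bg[, "x"] <- 1; inst$pres[, "x"] <- 1
  fit <- fit_maxent(inst$pres, inst$bg, classes = "L", rm = 1)
  pc <- percent_contribution(fit)
  expect_equal(unname(pc), 0, ignore_attr = TRUE)
  expect_true(attr(pc, "all_zero"))
  fit$trace <- NULL
  expect_error(percent_contribution(fit), "without a trace")
})

test_that("jackknife baselines behave on identity and noise-removal cases", {
  # one informative variable, one independent white-noise variable
  withr::with_seed(13, {
    bg <- cbind(sig = runif(500), noise = runif(500))
    pres <- cbind(sig = rnorm(60, 0.7, 0.08), noise = runif(60))
  })
  jk <- jackknife_importance(pres, bg, classes = "LQ", rm = 1)
  full_gain <- unname(attr(jk, "full")["train_gain"])
  # removing the white-noise variable barely changes the gain
  wo_noise <- jk$train_gain[jk$variable == "noise" & jk$mode == "without"]
  expect_lt(abs(wo_noise - full_gain) / full_gain, 0.05)
  # without-variable gain cannot exceed the full-model gain (up to tolerance)
  expect_true(all(jk$train_gain[jk$mode == "without"] <= full_gain + 1e-6))
  # the informative variable ranks first by with-only gain
  wo <- jk[jk$mode == "with_only", ]
  expect_equal(wo$variable[which.max(wo$train_gain)], "sig")

  # one-variable model: with-only equals the full fit exactly
  jk1 <- jackknife_importance(pres, bg, classes = "L", rm = 1)
  f1 <- fit_maxent(pres[, "sig", drop = FALSE],
                   bg[, "sig", drop = FALSE], classes = "L", rm = 1)
  expect_equal(jk1$train_gain[jk1$variable == "sig" & jk1$mode == "with_only"],
               f1$gain, tolerance = 1e-10)
})

test_that("fit contracts: errors on degenerate input, objective never decreases", {
  inst <- random_instance(n_bg = 60, m = 12, seed = 9)
  expect_error(fit_maxent(inst$pres[1, , drop = FALSE], inst$bg), "at least 2")
  expect_error(fit_maxent(inst$pres, inst$bg[1:5, ], ), "at least as large")
  expect_error(fit_maxent(inst$pres, inst$bg, rm = -1), "positive")
  bad <- inst$pres; bad[2, "b"] <- NA
  expect_error(fit_maxent(bad, inst$bg, classes = "L"), "non-finite")

  # monotone objective: refit while recording sweep-level objectives
  f1 <- fit_maxent(inst$pres, inst$bg, classes = "LQ", rm = 1, max_sweeps = 1)
  f2 <- fit_maxent(inst$pres, inst$bg, classes = "LQ", rm = 1, max_sweeps = 3)
  f3 <- fit_maxent(inst$pres, inst$bg, classes = "LQ", rm = 1, max_sweeps = 500)
  expect_true(f1$objective <= f2$objective + 1e-12)
  expect_true(f2$objective <= f3$objective + 1e-12)
})

test_that("models round-trip exactly through the plain-text serialization", {
  inst <- random_instance(n_bg = 80, m = 12, seed = 33)
  fit <- fit_maxent(inst$pres, inst$bg, classes = "LQH", rm = 0.7, n_knots = 6)
  path <- withr::local_tempfile(fileext = ".txt")
  write_maxent_model(fit, path)
  back <- read_maxent_model(path)
  expect_identical(back$lambda, fit$lambda)
  expect_identical(back$beta, fit$beta)
  expect_identical(back$logZ, fit$logZ)
  expect_identical(back$entropy, fit$entropy)
  expect_equal(predict(back, inst$bg), predict(fit, inst$bg), tolerance = 0)
})
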