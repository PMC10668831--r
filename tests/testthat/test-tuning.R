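test_that("candidate grids enumerate the Cartesian product in stated order", {
  g <- tuning_grid(rm = c(0.5, 1, 2), fc = c("L", "LQ", "LQH", "LQP", "LQPTH"))
  cand <- candidate_grid(g)
  expect_equal(nrow(cand), 15)
  # feature-combination major, RM minor
  expect_equal(cand$fc[1:3], rep("L", 3))
  expect_equal(cand$rm[1:3], c(0.5, 1, 2))
  g1 <- tuning_grid(rm = 1, fc = "LQ")
  expect_equal(nrow(candidate_grid(g1)), 1)
})

test_that("the default axes give 40 RM values and 31 subsets; the 29-entry axis gives 1160", {
  g <- tuning_grid()
  expect_equal(length(g$rm), 40)
  expect_equal(g$rm[1], 0.1)
  expect_equal(g$rm[40], 4.0)
  expect_equal(length(fc_grid_all()), 31)
  expect_equal(length(fc_grid_paper()), 29)
  expect_equal(nrow(candidate_grid(tuning_grid(fc = fc_grid_paper()))), 1160)
})

test_that("grid validation rejects malformed axes", {
  expect_error(tuning_grid(rm = numeric(0)), "empty")
  expect_error(tuning_grid(rm = c(1, 1)), "strictly increasing")
  expect_error(tuning_grid(rm = c(-1, 1)), "positive")
  expect_error(tuning_grid(fc = c("LQ", "QL")), "duplicate")
})

test_that("AICc follows the small-sample formula on a hand-computed case", {
  # n = 10, k = 3, lnL = -25: 6 + 50 + 24/6 = 60
  expect_equal(aicc(k = 3, lnL = -25, n = 10), 60)
  expect_true(is.na(aicc(k = 9, lnL = -25, n = 10)))
})

test_that("delta AICc is invariant to a constant shift in all lnL values", {
  k <- c(2, 5, 9); lnL <- c(-40, -35, -30); n <- 30
  d0 <- aicc(k, lnL, n) - min(aicc(k, lnL, n))
  d1 <- aicc(k, lnL + 7, n) - min(aicc(k, lnL + 7, n))
  expect_equal(d0, d1, tolerance = 1e-10)
})

test_that("scored candidates are deterministic and match serialized recomputation", {
  inst <- random_instance(n_bg = 120, m = 25, seed = 50)
  cand <- data.frame(fc = c("L", "LQ", "LQ"), rm = c(1, 1, 1),
                     stringsAsFactors = FALSE)
  scored <- score_candidates(cand, inst$pres, inst$bg)
  # duplicated settings score identically
  expect_equal(scored$AICc[2], scored$AICc[3], tolerance = 0)
  expect_equal(min(scored$delta_aicc, na.rm = TRUE), 0)
  expect_true(all(scored$delta_aicc >= 0, na.rm = TRUE))

  # oracle: recompute lnL and AICc from the serialized model's raw output
  mdl <- attr(scored, "models")[[1]]
  path <- withr::local_tempfile(fileext = ".txt")
  write_maxent_model(mdl, path)
  back <- read_maxent_model(path)
  raw_p <- predict(back, inst$pres, transform = "raw")
  lnL <- sum(log(raw_p))
  k <- sum(back$lambda != 0)
  expect_equal(scored$lnL[1], lnL, tolerance = 1e-10)
  expect_equal(scored$AICc[1], aicc(k, lnL, nrow(inst$pres)), tolerance = 1e-10)
})

test_that("overparameterized candidates are flagged invalid", {
  inst <- random_instance(n_bg = 100, m = 6, seed = 51)
  scored <- score_candidates(data.frame(fc = c("L", "LQPTH"), rm = c(1, 0.1)),
                             inst$pres, inst$bg, n_knots = 10)
  expect_true(scored$valid[1])
  if (scored$k[2] >= 5) {
    expect_false(scored$valid[2])
    expect_true(is.na(scored$delta_aicc[2]))
  }
  inst2 <- random_instance(n_bg = 60, m = 3, vars = c("a", "b", "c", "d"), seed = 2)
  expect_error(
    score_candidates(data.frame(fc = "LQPTH", rm = 0.01), inst2$pres, inst2$bg,
                     n_knots = 15),
    "invalid")
})

test_that("selection returns the delta = 0 candidate with documented tie-breaks", {
  scored <- data.frame(
    fc = c("L", "LQ", "LQH"), rm = c(2, 1, 0.5),
    k = c(7, 4, 4), lnL = c(-20, -21, -21),
    AICc = c(55, 55, 55), valid = TRUE, delta_aicc = c(0, 0, 0))
  class(scored) <- c("candidate_models", "data.frame")
  best <- select_best(scored)
  expect_equal(best$k, 4)       # smaller k wins the AICc tie
  expect_equal(best$rm, 0.5)    # then smaller RM
  single <- scored[2, ]; single$delta_aicc <- 0
  expect_equal(select_best(single)$fc, "LQ")
})

test_that("replicated fits are deterministic and average their own maps", {
  sc <- tiny_scenario()
  stk <- scenario_stack(sc, "current")
  occ <- thin_to_grid(sample_occurrences(sc, n = 80, seed = 3), stk)
  bg <- background_sample(stk, seed = 1)
  Xp <- presence_values(stk, occ)

  r1 <- replicate_fit(stk, Xp, bg$X, fc = "LQ", rm = 1, reps = 3, seed = 11)
  r2 <- replicate_fit(stk, Xp, bg$X, fc = "LQ", rm = 1, reps = 3, seed = 11)
  expect_identical(r1$mean_map$layers$suitability, r2$mean_map$layers$suitability)

  # single replicate: averaged map equals that replicate's map
  rs <- replicate_fit(stk, Xp, bg$X, fc = "LQ", rm = 1, reps = 1, seed = 5)
  expect_equal(rs$mean_map$layers$suitability, rs$maps[[1]]$layers$suitability)

  # cellwise mean lies between the replicate envelope, all within [0,1]
  mats <- lapply(r1$maps, function(m) m$layers$suitability)
  lo <- pmin(mats[[1]], mats[[2]], mats[[3]])
  hi <- pmax(mats[[1]], mats[[2]], mats[[3]])
  mu <- r1$mean_map$layers$suitability
  expect_true(all(mu >= lo - 1e-12 & mu <= hi + 1e-12, na.rm = TRUE))
  expect_true(all(mu >= 0 & mu <= 1, na.rm = TRUE))
  expect_error(replicate_fit(stk, Xp, bg$X, fc = "L", rm = 1, reps = 2,
                             test_percent = 0.1), "empty")
})
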