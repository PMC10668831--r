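test_that("identical epochs give pure stability; an empty future gives pure loss", {
  withr::with_seed(71, vals <- matrix(runif(100), 10, 10))
  cur <- suit_stack(vals)
  cm <- change_map(cur, cur)
  a <- attr(cm, "areas")
  expect_equal(a[["expansion"]], 0)
  expect_equal(a[["shrinkage"]], 0)
  suitable_area <- sum(cell_area_matrix(cur)[vals >= 0.05]) / 1e4
  expect_equal(a[["stable"]], suitable_area, tolerance = 1e-12)

  fut0 <- suit_stack(matrix(0, 10, 10))
  cm0 <- change_map(cur, fut0)
  a0 <- attr(cm0, "areas")
  expect_equal(a0[["stable"]], 0)
  expect_equal(a0[["expansion"]], 0)
  expect_equal(a0[["shrinkage"]], suitable_area, tolerance = 1e-12)
})

test_that("overlay states match a brute-force set-operation recount", {
  withr::with_seed(72, {
    cur <- matrix(runif(400), 20, 20)
    fut <- matrix(runif(400), 20, 20)
  })
  cur[2, 3] <- NA
  cm <- change_map(suit_stack(cur), suit_stack(fut), threshold = 0.3)
  valid <- !is.na(cur) & !is.na(fut)
  c_suit <- valid & cur >= 0.3
  f_suit <- valid & fut >= 0.3
  expected <- c(sum(valid & !c_suit & !f_suit), sum(c_suit & f_suit),
                sum(!c_suit & f_suit & valid), sum(c_suit & !f_suit))
  got <- sapply(0:3, function(k) sum(cm$layers$change == k, na.rm = TRUE))
  expect_equal(got, expected)
})

test_that("change areas obey the conservation identities exactly", {
  withr::with_seed(73, {
    cur <- matrix(runif(300), 15, 20)
    fut <- matrix(runif(300), 15, 20)
  })
  scur <- suit_stack(cur); sfut <- suit_stack(fut)
  a <- attr(change_map(scur, sfut), "areas")
  area_mat <- cell_area_matrix(scur)
  current_suit <- sum(area_mat[cur >= 0.05]) / 1e4
  future_suit <- sum(area_mat[fut >= 0.05]) / 1e4
  expect_equal(a[["stable"]] + a[["shrinkage"]], current_suit, tolerance = 1e-12)
  expect_equal(a[["stable"]] + a[["expansion"]], future_suit, tolerance = 1e-12)
  expect_error(change_map(scur, suit_stack(matrix(0.5, 5, 5))), "co-registered")
})

test_that("centroids reduce to cell centres and respect symmetry", {
  vals <- matrix(0, 5, 5); vals[2, 4] <- 1
  stk <- suit_stack(vals, xll = 100, yll = 30, cellsize = 1)
  cen <- centroid(stk, threshold = 0.5)
  expect_equal(cen$lon, cell_lons(stk)[4])
  expect_equal(cen$lat, cell_lats(stk)[2])

  # region symmetric about a meridian: centroid sits on it
  vals2 <- matrix(0, 5, 5); vals2[3, 2:4] <- 1
  cen2 <- centroid(suit_stack(vals2, xll = 100, yll = 30, cellsize = 1), 0.5)
  expect_equal(cen2$lon, mean(cell_lons(suit_stack(vals2, 100, 30, 1))[2:4]))
  expect_error(centroid(suit_stack(matrix(0, 3, 3))), "no suitable cells")
})

test_that("centroids equal an independent area-weighted recomputation", {
  withr::with_seed(74, vals <- matrix(runif(200), 10, 20))
  stk <- suit_stack(vals, xll = 100, yll = 24, cellsize = 0.5)
  cen <- centroid(stk, threshold = 0.4)
  lats <- cell_lats(stk); lons <- cell_lons(stk)
  num_lat <- 0; num_lon <- 0; den <- 0
  for (r in 1:10) for (c in 1:20) {
    if (vals[r, c] >= 0.4) {
      w <- cell_area_km2(stk)[r]
      num_lat <- num_lat + w * lats[r]
      num_lon <- num_lon + w * lons[c]
      den <- den + w
    }
  }
  expect_equal(cen$lat, num_lat / den, tolerance = 1e-12)
  expect_equal(cen$lon, num_lon / den, tolerance = 1e-12)
})

test_that("migration vectors reproduce closed-form geodesics", {
  a <- list(lat = 0, lon = 10)
  b <- list(lat = 1, lon = 10)
  mig <- migration(a, b)   # one degree due north along a meridian
  expect_equal(mig$distance_km, 6371 * pi / 180, tolerance = 1e-9)
  expect_equal(mig$bearing_deg, 0)
  expect_equal(mig$label, "N")
  same <- migration(a, a)
  expect_equal(same$distance_km, 0)
})

test_that("distance and bearing agree with an independent geodesic library", {
  skip_if_not_installed("geosphere")
  pts <- list(list(lat = 29.42, lon = 109.74), list(lat = 29.49, lon = 110.21),
              list(lat = 29.53, lon = 110.74), list(lat = 29.61, lon = 110.02))
  for (i in 1:3) {
    a <- pts[[i]]; b <- pts[[i + 1]]
    mig <- migration(a, b)
    d_ref <- geosphere::distHaversine(c(a$lon, a$lat), c(b$lon, b$lat),
                                      r = 6371000) / 1000
    b_ref <- geosphere::bearing(c(a$lon, a$lat), c(b$lon, b$lat)) %% 360
    expect_equal(mig$distance_km, d_ref, tolerance = 1e-6)
    expect_equal(mig$bearing_deg, b_ref, tolerance = 0.2)
  }
})

test_that("compass labels cover the eight 45-degree sectors", {
  expect_equal(compass_label(c(0, 45, 90, 135, 180, 225, 270, 315)),
               c("N", "NE", "E", "SE", "S", "SW", "W", "NW"))
  expect_equal(compass_label(c(22.4, 22.5, 359)), c("N", "NE", "N"))
})
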