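# Density distribution, thresholds, interpolation and re-initialization.

test_that("biomass fractions follow the stock shares", {
  st <- one_cell_state(n_pft = 1)
  st$eq[1, "v", 1] <- 20; st$eq[1, "s", 1] <- 20
  f <- compute_biomass_fractions(st)
  expect_equal(unname(f[1, , 1]), c(0.5, 0.5))

  st$eq[1, "v", 1] <- 40; st$eq[1, "s", 1] <- 0
  f <- compute_biomass_fractions(st)
  expect_equal(unname(f[1, , 1]), c(1, 0))

  st$eq[1, "v", 1] <- 30; st$eq[1, "s", 1] <- 10
  f <- compute_biomass_fractions(st)
  expect_equal(unname(f[1, , 1]), c(0.75, 0.25))
})

test_that("zero-stock cells fall back to static area weights", {
  st <- one_cell_state(cover = c(v = 0.6, s = 0.2, c = 0.1, p = 0.1),
                       n_pft = 1)
  f <- compute_biomass_fractions(st)
  expect_equal(unname(f[1, , 1]), c(0.75, 0.25))
})

test_that("density distribution conserves the cell stock exactly", {
  f <- array(0, c(1, 2, 1)); f[1, , 1] <- c(0.6, 0.4)
  out <- distribute_density(100, 1000, f)
  expect_equal(unname(out[1, , 1]), c(60000, 40000))
  expect_equal(sum(distribute_density(0, 1000, f)), 0)
  # conservation for random inputs
  set.seed(3)
  for (i in 1:20) {
    fr <- stats::runif(16); fr <- fr / sum(fr)
    f2 <- array(fr, c(1, 2, 8))
    rho <- stats::runif(1, 0, 300); A <- stats::runif(1, 100, 1e6)
    expect_equal(sum(distribute_density(rho, A, f2)), rho * A,
                 tolerance = 1e-12)
  }
  expect_error(distribute_density(-1, 10, f), "negative")
})

test_that("per-slot densities invert the distribution", {
  st0 <- array(0, c(1, 2, 1))
  expect_equal(sum(derive_cell_densities(st0, array(0.5, c(1, 2, 1)), 10)), 0)

  stocks <- array(c(500, 0), c(1, 2, 1))
  frac <- array(c(0.1, 0.2), c(1, 2, 1))
  d <- derive_cell_densities(stocks, frac, 100)   # 500 tC on 10 ha
  expect_equal(d[1, 1, 1], 50)

  # round trip: distribute then derive reproduces the cell density
  f <- array(c(0.5, 0.5), c(1, 2, 1))
  C <- distribute_density(80, 1000, f)
  d2 <- derive_cell_densities(C, f, 1000)
  expect_equal(unname(d2[1, , 1]), c(80, 80))

  bad <- array(c(1, 0), c(1, 2, 1))
  expect_error(derive_cell_densities(bad, array(0, c(1, 2, 1)), 10),
               "zero-area")
})

test_that("uniform threshold masks at the stated limit", {
  ser <- array(c(380, 100, 374.9, 375), c(4, 1, 1, 1))
  out <- apply_thresholds(ser, threshold_policy("uniform"))
  expect_equal(as.vector(out$mask), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(nrow(out$report), 2)
  expect_error(apply_thresholds(array(NA_real_, c(1, 1, 1, 1)),
                                threshold_policy("uniform")), "empty")
})

test_that("percentile threshold matches the brute-force cutoff and is a
           superset of the uniform exclusions", {
  vals <- c(1:100, 380, 500)            # two uniform outliers
  ser <- array(vals, c(length(vals), 1, 1, 1))
  pol <- threshold_policy("percentile", percentile = 97)
  out <- apply_thresholds(ser, pol)
  # brute-force: sort the values below 375 and take the type-7 quantile
  below <- sort(vals[vals < 375])
  h <- (length(below) - 1) * 0.97 + 1
  cut_bf <- below[floor(h)] + (h - floor(h)) *
    (below[ceiling(h)] - below[floor(h)])
  expect_equal(out$cutoffs[1, 1], cut_bf)
  expect_equal(which(as.vector(out$mask)),
               which(vals >= 375 | (vals < 375 & vals > cut_bf)))

  uni <- apply_thresholds(ser, threshold_policy("uniform"))
  expect_true(all(as.vector(uni$mask) <= as.vector(out$mask)))
})

test_that("threshold policies are applied per cover/PFT layer", {
  set.seed(9)
  ser <- array(stats::runif(2 * 5 * 2 * 2, 0, 300), c(5, 2, 2, 2))
  out <- apply_thresholds(ser, threshold_policy("percentile",
                                                percentile = 80))
  for (j in 1:2) for (l in 1:2) {
    v <- as.vector(ser[, , j, l])
    cut <- stats::quantile(v[v < 375], 0.8, type = 7, names = FALSE)
    expect_equal(as.vector(out$mask[, , j, l]), v > cut)
  }
})

test_that("barycentric interpolation is exact on planar fields", {
  g <- grid_spec(lat = seq(5, 1, by = -1) - 0.5, lon = seq(1, 6) - 0.5)
  co <- cell_coords(g)
  plane <- 2 * co[, "lon"] + 3 * co[, "lat"]

  # identity on a complete field
  expect_identical(interpolate_missing(plane, g), plane)

  # constant field reproduced
  cst <- rep(4.2, g$n_cell); cst[c(7, 18)] <- NA
  expect_equal(interpolate_missing(cst, g), rep(4.2, g$n_cell))

  # planar field recovered exactly at interior and (non-corner) edge gaps;
  # corner gaps lie outside the hull of the remaining valid cells and take
  # the nearest valid value instead
  fld <- plane
  gaps <- c(3, 8, 13, 14, 15, 22)
  fld[gaps] <- NA
  got <- interpolate_missing(fld, g)
  expect_equal(got[gaps], plane[gaps], tolerance = 1e-9)
  expect_identical(got[-gaps], plane[-gaps])

  expect_error(interpolate_missing(c(NA, NA, 1, NA), grid_spec(
    lat = c(1.5, 0.5), lon = c(0.5, 1.5))), "3 valid")
})

test_that("exterior gaps take the nearest valid value", {
  g <- grid_spec(lat = seq(4, 1) - 0.5, lon = seq(1, 4) - 0.5)
  fld <- rep(NA_real_, 16)
  # valid block in one corner; the far corner is outside the hull
  fld[c(1, 2, 5, 6)] <- c(1, 2, 3, 4)
  got <- interpolate_missing(fld, g)
  expect_false(anyNA(got))
  expect_equal(got[16], 4)    # nearest valid cell of the far corner
})

test_that("re-initialization reaches the fixed point and folds excess", {
  st <- one_cell_state(n_pft = 1)
  st$eq[1, "v", 1] <- 30; st$eq[1, "s", 1] <- 10
  C_as <- array(0, c(1, 2, 1)); C_as[1, , 1] <- c(30, 10)
  out <- reinitialize_pools(st, C_as)
  expect_equal(out$state$eq, st$eq)
  expect_equal(out$injection, 0)

  # main excess is folded into the legacy trackers
  st$exc[1, "s", "h", 1, "decay"] <- 2
  out2 <- reinitialize_pools(st, C_as)
  expect_equal(sum(abs(out2$state$exc)), 0)
  expect_equal(out2$state$leg_post[1, "s", "h", 1, "decay"], 2)

  # zero assimilated stocks zero the woody equilibrium pools
  out3 <- reinitialize_pools(st, C_as * 0)
  expect_equal(sum(out3$state$eq), 0)
  expect_equal(out3$injection, -40)

  expect_error(reinitialize_pools(st, C_as, mode = "fixed"), "transient")
})

test_that("re-initialization pins the living stock to the assimilated stock", {
  # with a tracked regrowth deficit, eq compensates so that living == C_as
  st <- one_cell_state(n_pft = 1)
  st$eq[1, "s", 1] <- 50
  st$leg_post[1, "s", "a", 1, "regrow"] <- -5
  C_as <- array(0, c(1, 2, 1)); C_as[1, , 1] <- c(0, 48)
  out <- reinitialize_pools(st, C_as)
  expect_equal(living_stock(out$state, "total"), 48)
  expect_equal(unname(out$state$eq[1, "s", 1]), 48 + 5)
})

test_that("screening completes a gappy series and conserves clean cells", {
  w <- generate_world(quiet_world_config())
  obs <- degrade_observations(w$truth_densities, noise_sd = 0,
                              missing_frac = 0.1, seed = 5)
  scr <- screen_density_series(obs, w$init_state, threshold_policy("uniform"))
  expect_true(all(scr$densities$valid))
  keep <- obs$valid
  expect_equal(scr$densities$values[keep], w$truth_densities$values[keep],
               tolerance = 1e-9)
})
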