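# Evaluation metrics: IAV, bias, agreement, intensity, detrending,
# Spearman maps, regional aggregation, uncertainty scaling.

test_that("IAV is the coefficient of variation", {
  expect_equal(iav(c(2, 2, 2)), 0)
  expect_equal(iav(c(1, 2, 3)), 0.5)
  set.seed(2)
  x <- stats::rlnorm(20)
  expect_equal(iav(3.7 * x), iav(x), tolerance = 1e-12)
  expect_error(iav(c(-1, 1)), "zero mean")
  expect_error(iav(5), "two values")
})

test_that("assimilation bias is the time-mean model-minus-observed stock", {
  a <- matrix(c(10, 20, 30, 40), 2, 2)
  expect_equal(assimilation_bias(a, a)$bias_field, c(0, 0))
  # constant +1 tC/ha offset on a single 1000-ha cell
  obs <- matrix(5:9, 5, 1) * 1000
  mod <- obs + 1 * 1000
  b <- assimilation_bias(mod, obs)
  expect_equal(b$bias_field, 1000)
  expect_equal(b$global_mean, 1000 * 1e-9)
  expect_equal(b$global_sd, 0)
  # antisymmetry
  b2 <- assimilation_bias(obs, mod)
  expect_equal(b2$bias_field, -b$bias_field)
  expect_error(assimilation_bias(a, a[1, , drop = FALSE]), "misaligned")
})

test_that("temporal agreement counts matching year-over-year trends", {
  expect_equal(temporal_agreement(1:5, 1:5), 1)
  expect_equal(temporal_agreement(1:5, -(1:5)), 0)
  expect_equal(temporal_agreement(c(0, 1, 0, 1), c(0, 1, 2, 3)), 2 / 3)
  # zero changes agree only with zero changes
  expect_equal(temporal_agreement(c(1, 1, 2), c(3, 3, 1)), 0.5)
  # symmetry
  set.seed(4)
  x <- stats::rnorm(10); y <- stats::rnorm(10)
  expect_equal(temporal_agreement(x, y), temporal_agreement(y, x))
  expect_error(temporal_agreement(1, 1), "two values")
})

test_that("land-use intensity is the mean cleared+harvested percentage", {
  fo <- transition_forcing(2000:2004, 2)
  expect_equal(lulcc_intensity(fo), c(0, 0))
  cl <- array(0, c(5, 2, 2, 2)); cl[, , 1, 1] <- 0.02
  fo2 <- transition_forcing(2000:2004, 2, clearing = cl,
                            harvest = matrix(0.03, 5, 2))
  expect_equal(lulcc_intensity(fo2), c(5, 5))
  # abandonment does not count
  ab <- array(0, c(5, 2, 2)); ab[, , 1] <- 0.1
  fo3 <- transition_forcing(2000:2004, 2, abandonment = ab)
  expect_equal(lulcc_intensity(fo3), c(0, 0))
})

test_that("detrending removes linear structure and is idempotent", {
  expect_equal(detrend(2 + 3 * (1:10)), rep(0, 10), tolerance = 1e-12)
  expect_equal(detrend(rep(7, 5)), rep(0, 5), tolerance = 1e-12)
  expect_equal(detrend(c(0, 2, 1)), c(-0.5, 1, -0.5), tolerance = 1e-12)
  set.seed(5)
  x <- stats::rnorm(12) + 0.3 * (1:12)
  expect_equal(sum(detrend(x)), 0, tolerance = 1e-9)
  expect_equal(detrend(detrend(x)), detrend(x), tolerance = 1e-10)
  expect_error(detrend(c(1, 2)), "three points")
})

test_that("Spearman correlation matches the rank formula with exact p", {
  expect_equal(spearman_test(1:6, (1:6)^3)$rho, 1)
  expect_equal(spearman_test(1:6, -(1:6))$rho, -1)
  st <- spearman_test(c(1, 2, 3, 4), c(1, 3, 2, 4))
  d2 <- sum((rank(c(1, 2, 3, 4)) - rank(c(1, 3, 2, 4)))^2)
  expect_equal(st$rho, 1 - 6 * d2 / (4 * 15))
  expect_equal(st$rho, 0.8)
  # exact permutation p at n=4: share of |rho| >= 0.8 among 24 permutations
  expect_equal(st$p, 1 / 3)
  # invariance under strictly monotone transforms
  set.seed(6)
  x <- stats::rnorm(15); y <- stats::rnorm(15)
  r0 <- spearman_test(x, y)$rho
  expect_equal(spearman_test(exp(x), y)$rho, r0)
  expect_equal(spearman_test(x, y^3 + 5 * y)$rho, r0)
  # constant series are undefined
  expect_true(is.na(spearman_test(rep(1, 5), 1:5)$rho))
})

test_that("large-sample p agrees with cor.test's t approximation", {
  set.seed(8)
  x <- stats::rnorm(30); y <- x + stats::rnorm(30)
  got <- spearman_test(x, y)
  ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(got$rho, unname(ref$estimate))
  expect_equal(got$p, ref$p.value, tolerance = 1e-9)
})

test_that("spearman maps flag coupled cells on synthetic worlds", {
  # biomass anomalies generated as a monotone function of temperature
  # anomalies plus small noise: expect strong positive correlations
  w <- generate_world(synthetic_world_config(
    n_lat = 4, n_lon = 4, years = 2000:2014, seed = 12,
    temp_coupling = 0.04, temp_sd = 1, clearing_rate = 0,
    harvest_rate = 0, abandon_rate = 0, missing_frac = 0, noise_sd = 0))
  d <- bkm_decompose(w$densities, w$forcing, w$init_state)
  sm <- spearman_map(d$runs$transient$stocks, w$climate$temperature)
  expect_true(stats::median(sm$rho, na.rm = TRUE) > 0.7)
  expect_true(mean(sm$significant) > 0.5)
  # uncoupled variable: no systematic correlation
  sp <- spearman_map(d$runs$transient$stocks, w$climate$precipitation)
  expect_lt(abs(stats::median(sp$rho, na.rm = TRUE)), 0.5)
})

test_that("regional aggregation is area-weighted and partitions the total", {
  # 3-cell toy: areas (1,2,3) ha, density 1 tC/ha, regions (A,A,B)
  fld <- matrix(1, 2, 3)
  out <- regional_aggregate(fld, c(1, 1, 2), areas = c(1, 2, 3))
  expect_equal(out, matrix(3, 2, 2), ignore_attr = TRUE)
  # single region equals the global series
  v <- matrix(stats::rnorm(12), 3, 4)
  expect_equal(as.vector(regional_aggregate(v, rep(1, 4))), rowSums(v))
  # regions partition the global sum
  set.seed(10)
  mask <- sample(1:3, 4, replace = TRUE)
  expect_equal(rowSums(regional_aggregate(v, mask)), rowSums(v),
               tolerance = 1e-12)
  expect_error(regional_aggregate(v, 1:3), "cover")
})

test_that("uncertainty scaling gives symmetric bounds", {
  u <- scale_uncertainty(381, 0.005)
  expect_equal(u$half_width, 1.905)
  expect_equal(u$upper - u$lower, 2 * 1.905)
  expect_equal(scale_uncertainty(50, 0)$half_width, 0)
  expect_equal(scale_uncertainty(100, 0.01)$half_width, 1)
  expect_error(scale_uncertainty(1, -0.1), ">= 0")
})

test_that("the diagnostics wrapper assembles all metrics", {
  w <- generate_world(quiet_world_config())
  d <- bkm_decompose(w$densities, w$forcing, w$init_state)
  dg <- bkm_diagnostics(d, w$forcing, climate = w$climate,
                        region_mask = rep(1:2, each = 8))
  expect_s3_class(dg, "bkm_diagnostics")
  expect_true(dg$temporal_agreement >= 0 && dg$temporal_agreement <= 1)
  expect_length(dg$lulcc_intensity, 16)
  expect_equal(rowSums(dg$regional_stocks), rowSums(d$runs$transient$stocks),
               tolerance = 1e-12)
  expect_true(all(abs(dg$correlations$temperature$rho) <= 1, na.rm = TRUE))
})
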