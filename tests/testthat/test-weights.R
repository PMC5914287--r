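flat_elev <- function(z, nr = 4, nc = 4) {
  value_raster(grid_spec(nr, nc), matrix(z, nr, nc), name = "elevation_m")
}

test_that("inhabitability excludes highland, water, protected and low tracts", {
  spec <- grid_spec(4, 4)
  z <- matrix(100, 4, 4); z[1, 1] <- 3600
  elev <- value_raster(spec, z)
  water <- label_raster(spec, {
    m <- matrix(0, 4, 4); m[2, 2] <- 1; m
  })
  prot <- label_raster(spec, {
    m <- matrix(0, 4, 4); m[3, 3] <- 1; m
  })
  w0 <- inhabitability_mask(elev, water, prot)
  expect_equal(w0$data[1, 1], 0)  # above 3500 m
  expect_equal(w0$data[2, 2], 0)  # water
  expect_equal(w0$data[3, 3], 0)  # protected
  expect_equal(w0$data[4, 4], 1)  # plain lowland
})

test_that("only water patches at or above the minimum size are masked", {
  spec <- grid_spec(6, 6)
  m <- matrix(0, 6, 6)
  m[1, 1:3] <- 1            # 3-pixel patch
  m[5, 5] <- 1              # isolated pixel
  w0 <- inhabitability_mask(flat_elev(10, 6, 6), label_raster(spec, m),
                            config = inhabitability_config(
                              min_water_patch_km2 = 3))
  expect_equal(unname(w0$data[1, 1:3]), c(0, 0, 0))
  expect_equal(w0$data[5, 5], 1)  # below the patch threshold
})

test_that("low-population tracts are masked by their division's cutoff", {
  spec <- grid_spec(4, 4)
  tr <- label_raster(spec, matrix(rep(1:2, each = 8), 4, 4), "tract")
  dv <- label_raster(spec, matrix(rep(1:2, each = 8), 4, 4), "division")
  w0 <- inhabitability_mask(
    flat_elev(50), tract_labels = tr,
    tract_populations = c("1" = 1500, "2" = 1500),
    config = inhabitability_config(cutoff_population = c("1" = 2000,
                                                         "2" = 1000)),
    division_labels = dv)
  expect_true(all(w0$data[tr$data == 1] == 0))  # 1500 < cutoff 2000
  expect_true(all(w0$data[tr$data == 2] == 1))  # 1500 >= cutoff 1000
})

test_that("exact log-density data is recovered by the regional topo fit", {
  z <- seq(0, 2000, length.out = 12)
  pd <- exp(-0.001 * z + 5)
  fit <- fit_topo_relation(pd, z, region = 3)
  expect_equal(fit$m, -0.001, tolerance = 1e-12)
  expect_equal(fit$b, 5, tolerance = 1e-10)
  expect_true(fit$weighted)
})

test_that("degenerate topo inputs raise fit errors", {
  expect_error(fit_topo_relation(c(1, 2), c(0, 10)), "fewer than 3")
  expect_error(fit_topo_relation(c(1, 2, 3), c(5, 5, 5)), "zero variance")
})

test_that("an insignificant slope turns topographic weighting off", {
  withr::with_seed(3, {
    z <- stats::runif(10, 0, 100)          # tiny elevation span
    pd <- exp(stats::rnorm(10, 4, 1))      # density unrelated to z
  })
  fit <- fit_topo_relation(pd, z, region = 0)
  expect_false(fit$weighted)
  w1 <- topo_weight(flat_elev(1000), fit)
  expect_true(all(w1$data == 1))
})

test_that("noisy regional fits recover the generator slope within 15%", {
  sim <- simulate_county_topo(40, m = -0.001, noise_sd = 0.3, seed = 21)
  fit <- fit_topo_relation(sim$density_per_km2, sim$mean_elevation_m)
  expect_lt(abs(fit$m - (-0.001)) / 0.001, 0.15)
})

test_that("w1 is the exponential of slope times elevation", {
  fit <- structure(list(region = 1, m = -0.001, b = 0, p_value = 0,
                        weighted = TRUE, n_fit = 10, band = NULL),
                   class = "region_topo_fit")
  w1 <- topo_weight(flat_elev(1000), fit)
  expect_equal(w1$data[1, 1], exp(-1), tolerance = 1e-12)
  fit$m <- 0
  expect_true(all(topo_weight(flat_elev(1000), fit)$data == 1))
})

test_that("banded fits apply only inside their elevation band", {
  spec <- grid_spec(2, 2)
  elev <- value_raster(spec, matrix(c(50, 150, 250, 350), 2, 2))
  reg <- label_raster(spec, matrix(1, 2, 2), "region")
  mk <- function(m, band) structure(
    list(region = 1, m = m, b = 0, p_value = 0, weighted = TRUE,
         n_fit = 5, band = band), class = "region_topo_fit")
  w1 <- topo_weight(elev, list(mk(-0.01, c(0, 200)), mk(-0.002, c(200, Inf))),
                    reg)
  expect_equal(w1$data[1, 1], exp(-0.01 * 50))
  expect_equal(w1$data[1, 2], exp(-0.002 * 250))
})

test_that("intra-urban weight decays as an inverse power of distance", {
  spec <- grid_spec(9, 9)
  cen <- c(row = 5, col = 5)
  px <- which(matrix(TRUE, 9, 9))
  expect_true(all(urban_distance_weight(px, cen, 0, spec) == 1))
  # pixel two cells east: r = 2 km, lambda = 1 -> 0.5
  east2 <- (7 - 1) * 9 + 5
  expect_equal(urban_distance_weight(east2, cen, 1, spec), 0.5)
  # ring distances match direct power evaluation, monotone in r
  ring <- c((6 - 1) * 9 + 5, (7 - 1) * 9 + 5, (9 - 1) * 9 + 5)  # r = 1,2,4
  w <- urban_distance_weight(ring, cen, 0.10, spec)
  expect_equal(w, c(1, 2, 4)^(-0.10), tolerance = 1e-14)
  expect_true(all(diff(w) < 0))
  # the center pixel is clamped at half a cell, not infinite
  cen_px <- (5 - 1) * 9 + 5
  expect_equal(urban_distance_weight(cen_px, cen, 1, spec), 2)
})

test_that("gravity weight reduces to P for a single in-range urban area", {
  spec <- grid_spec(10, 10)
  px <- which(matrix(TRUE, 10, 10))
  w <- market_potential(px, matrix(c(3, 3), 1), 12345, d_max_km = 50, spec)
  expect_true(all(abs(w - 12345) < 1e-9))
})

test_that("equal-population sources give the common population in joint range", {
  spec <- grid_spec(10, 10)
  px <- which(matrix(TRUE, 10, 10))
  cents <- rbind(c(2, 2), c(9, 9))
  w <- market_potential(px, cents, c(5000, 5000), d_max_km = 100, spec)
  expect_true(all(abs(w - 5000) < 1e-9))
})

test_that("gravity weights match a brute-force double loop", {
  spec <- grid_spec(5, 5)
  px <- which(matrix(TRUE, 5, 5))
  cents <- rbind(c(1, 1), c(3, 4), c(5, 2))
  pops <- c(4000, 9000, 2600)
  got <- market_potential(px, cents, pops, d_max_km = 100, spec)
  brute <- vapply(px, function(p) {
    r <- ((p - 1) %% 5) + 1; cc <- ((p - 1) %/% 5) + 1
    num <- 0; den <- 0
    for (j in 1:3) {
      rij <- max(sqrt((r - cents[j, 1])^2 + (cc - cents[j, 2])^2), 0.5)
      num <- num + pops[j] / rij^2
      den <- den + 1 / rij^2
    }
    num / den
  }, numeric(1))
  expect_equal(got, brute, tolerance = 1e-12)
  # weighted-mean property: bounded by the population range
  expect_true(all(got >= min(pops) - 1e-9 & got <= max(pops) + 1e-9))
})

test_that("pixels with no urban area in range get the neutral weight", {
  spec <- grid_spec(10, 10)
  far <- (10 - 1) * 10 + 10  # corner opposite the source
  w <- market_potential(far, matrix(c(1, 1), 1), 8000, d_max_km = 3, spec)
  expect_equal(w, 1)
  expect_equal(market_potential(far, NULL, numeric(0), 10, spec), 1)
})

test_that("travel range interpolates log-linearly between anchors", {
  sch <- travel_schedule()
  expect_equal(travel_range(1790, sch), 30)
  expect_equal(travel_range(2000, sch), 100)
  expect_equal(travel_range(1895, sch), sqrt(30 * 100), tolerance = 1e-12)
  # clamped outside the anchor span
  expect_equal(travel_range(1700, sch), 30)
  expect_equal(travel_range(2050, sch), 100)
  expect_error(travel_schedule(c("1790" = -1, "2000" = 100)),
               "config error")
  expect_error(travel_schedule(c("1790" = 100, "2000" = 30)),
               "nondecreasing")
})

test_that("rescaling a weight layer within a zone leaves allocation unchanged", {
  withr::with_seed(8, {
    w1 <- stats::runif(15, 0.2, 2)
    w2 <- stats::runif(15, 0.2, 2)
  })
  base <- allocate_zone(1000, rep(1, 15), w1, w2, s = 1.3, d = 0.7)
  scaled <- allocate_zone(1000, rep(1, 15), 7.3 * w1, 0.11 * w2,
                          s = 1.3, d = 0.7)
  expect_equal(base$population, scaled$population, tolerance = 1e-12)
})

test_that("normalize_weights caps each division's maximum at one", {
  spec <- grid_spec(4, 4)
  w <- value_raster(spec, matrix(1:16, 4, 4))
  dv <- label_raster(spec, matrix(rep(1:2, each = 8), 4, 4))
  nw <- normalize_weights(w, dv)
  expect_equal(max(nw$data[dv$data == 1]), 1)
  expect_equal(max(nw$data[dv$data == 2]), 1)
  expect_equal(max(normalize_weights(w)$data), 1)
})
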