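test_that("allocate_zone spreads population proportionally to weights", {
  al <- allocate_zone(100, rep(1, 4))
  expect_equal(al$population, rep(25, 4))
  al2 <- allocate_zone(100, rep(1, 3), w1 = c(2, 1, 1), s = 1, d = 1)
  expect_equal(al2$population, c(50, 25, 25))
  expect_false(al2$fallback)
})

test_that("allocate_zone matches the brute-force normalized product", {
  withr::with_seed(31, {
    for (i in 1:25) {
      n <- 20
      w0 <- sample(0:1, n, replace = TRUE, prob = c(0.2, 0.8))
      w1 <- stats::runif(n, 0.1, 3)
      w2 <- stats::runif(n, 0.1, 3)
      s <- stats::runif(1, 0, 3); d <- stats::runif(1, 0, 3)
      pz <- stats::runif(1, 10, 1e5)
      got <- allocate_zone(pz, w0, w1, w2, s, d)
      brute <- numeric(n)
      tot <- 0
      for (k in 1:n) tot <- tot + w0[k] * w1[k]^s * w2[k]^d
      for (k in 1:n) brute[k] <- w0[k] * w1[k]^s * w2[k]^d / tot * pz
      expect_equal(got$population, brute, tolerance = 1e-12)
      expect_equal(sum(got$population), pz, tolerance = 1e-9)
    }
  })
})

test_that("an all-zero-weight zone falls back to uniform allocation", {
  al <- allocate_zone(90, w0 = rep(0, 3))
  expect_true(al$fallback)
  expect_equal(al$population, rep(30, 3))
  expect_error(allocate_zone(10, numeric(0)), "empty zone")
  expect_equal(allocate_zone(0, numeric(0))$population, numeric(0))
})

test_that("M1 allocates county totals homogeneously", {
  spec <- grid_spec(4, 4)
  counties <- label_raster(spec, matrix(rep(1:2, each = 8), 4, 4),
                           "county")
  census <- data.frame(unit_id = 1:2, decade = 2000,
                       population = c(800, 1600))
  res <- run_model("M1", 2000, counties, census)
  expect_true(all(res$raster$data[counties$data == 1] == 100))
  expect_true(all(res$raster$data[counties$data == 2] == 200))
})

test_that("M2 splits urban and rural, uniform within each", {
  spec <- grid_spec(4, 4)
  counties <- label_raster(spec, matrix(1, 4, 4), "county")
  ext <- matrix(0L, 4, 4); ext[1:2, 1:2] <- 5L
  extent <- label_raster(spec, ext, "urban")
  census <- data.frame(unit_id = 1, decade = 2000, population = 10400)
  up <- data.frame(urban_id = 5L, county = 1L, population = 8000)
  res <- run_model("M2", 2000, counties, census, extent, up)
  expect_true(all(res$raster$data[ext == 5L] == 2000))  # 8000 over 4 px
  expect_true(all(res$raster$data[ext == 0L] == 200))   # 2400 over 12 px
})

test_that("missing urban populations or infeasible tables raise errors", {
  spec <- grid_spec(4, 4)
  counties <- label_raster(spec, matrix(1, 4, 4), "county")
  ext <- matrix(0L, 4, 4); ext[1, 1] <- 9L
  extent <- label_raster(spec, ext, "urban")
  census <- data.frame(unit_id = 1, decade = 2000, population = 5000)
  expect_error(
    run_model("M2", 2000, counties, census, extent,
              data.frame(urban_id = integer(0), county = integer(0),
                         population = numeric(0))),
    "lack urban population")
  expect_error(
    run_model("M2", 2000, counties, census, extent,
              data.frame(urban_id = 9L, county = 1L, population = 6000)),
    "inconsistency error")
})

test_that("every model conserves county census totals", {
  w <- small_world()
  inp <- small_inputs()
  census <- inp$tables$census
  for (mo in c("M1", "M2", "M3", "M4", "M5")) {
    res <- run_history(mo, w$config$decades, w$counties, census,
                       extent_rasters = inp$extents$extent_rasters,
                       registry = w$registry, w0 = inp$w0, w1 = inp$w1,
                       w2 = inp$w2, s = 1, d = 0.6)
    for (t in names(res)) {
      got <- zonal_sum(res[[t]]$raster, w$counties)
      cen <- census[census$decade == as.integer(t), ]
      obs <- stats::setNames(cen$population, cen$unit_id)
      expect_lt(max(abs(got[names(obs)] - obs) / obs), 1e-6,
                label = sprintf("%s decade %s conservation", mo, t))
      expect_true(all(res[[t]]$raster$data >= 0, na.rm = TRUE))
    }
  }
})

test_that("exponent zero collapses each model onto the simpler one", {
  w <- small_world()
  inp <- small_inputs()
  census <- inp$tables$census
  ext <- inp$extents$extent_rasters[["2000"]]
  up <- urban_populations(w$registry, 2000)
  m3 <- run_model("M3", 2000, w$counties, census, ext, up, w0 = inp$w0)
  m4_0 <- run_model("M4", 2000, w$counties, census, ext, up,
                    w0 = inp$w0, w1 = inp$w1, s = 0)
  expect_identical(m4_0$raster$data, m3$raster$data)
  m4 <- run_model("M4", 2000, w$counties, census, ext, up,
                  w0 = inp$w0, w1 = inp$w1, s = 1)
  m5_0 <- run_model("M5", 2000, w$counties, census, ext, up,
                    w0 = inp$w0, w1 = inp$w1, w2 = inp$w2[["2000"]],
                    s = 1, d = 0)
  expect_identical(m5_0$raster$data, m4$raster$data)
})

test_that("per-division exponents are honored", {
  w <- small_world()
  inp <- small_inputs()
  ext <- inp$extents$extent_rasters[["2000"]]
  up <- urban_populations(w$registry, 2000)
  res_v <- run_model("M4", 2000, w$counties, inp$tables$census, ext, up,
                     w0 = inp$w0, w1 = inp$w1,
                     s = c("1" = 1, "2" = 0), divisions = w$divisions)
  res_1 <- run_model("M4", 2000, w$counties, inp$tables$census, ext, up,
                     w0 = inp$w0, w1 = inp$w1, s = 1)
  d1 <- w$divisions$data == 1
  expect_identical(res_v$raster$data[d1], res_1$raster$data[d1])
  d2px <- w$divisions$data == 2
  expect_false(identical(res_v$raster$data[d2px],
                         res_1$raster$data[d2px]))
})

test_that("run_history honors skip lists and is reproducible", {
  w <- small_world()
  inp <- small_inputs()
  res <- run_history("M1", w$config$decades, w$counties,
                     inp$tables$census, skip_decades = 1980)
  expect_named(res, c("1970", "1990", "2000"))
  res2 <- run_history("M1", w$config$decades, w$counties,
                      inp$tables$census, skip_decades = 1980)
  expect_identical(lapply(res, function(r) r$raster$data),
                   lapply(res2, function(r) r$raster$data))
  expect_error(
    run_history("M1", 1940, w$counties, inp$tables$census),
    "decade 1940")
})

test_that("M5 with the true exponents reproduces the generative truth", {
  w <- exact_world()
  tb <- world_to_census(w)
  t <- 2000
  up <- urban_populations(w$registry, t)
  w2 <- build_w2(t, w$extents[["2000"]], w$registry,
                 w$truth_params$scaling, w$counties,
                 w$truth_params$schedule)
  res <- run_model("M5", t, w$counties, tb$census, w$extents[["2000"]],
                   up, w0 = w$w0, w1 = w$w1, w2 = w2,
                   s = w$config$true_s, d = w$config$true_d)
  expect_equal(res$raster$data, w$truth[["2000"]]$data, tolerance = 1e-9)
})
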