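test_that("MARE matches hand arithmetic", {
  o <- c(a = 100, b = 100, c = 500)
  expect_equal(mare(o, o)$mare, 0)
  expect_equal(mare(2 * o, o)$mare, 1.0)
  m <- c(a = 110, b = 80, c = 400)
  sc <- mare(m, o)
  expect_equal(sc$mare, (0.1 + 0.2 + 0.2) / 3, tolerance = 1e-12)
  expect_equal(sc$n_units, 3L)
})

test_that("MARE is scale-free", {
  withr::with_seed(5, {
    o <- stats::setNames(stats::runif(20, 10, 1000), paste0("u", 1:20))
    m <- o * stats::runif(20, 0.5, 2)
  })
  expect_equal(mare(m, o)$mare, mare(17.3 * m, 17.3 * o)$mare,
               tolerance = 1e-12)
})

test_that("sub-resolution and zero-population units are excluded", {
  o <- c(a = 100, b = 200, c = 0, d = 400)
  m <- c(a = 150, b = 200, c = 10, d = 400)
  areas <- c(a = 0.5, b = 2, c = 2, d = 2)
  expect_warning(sc <- mare(m, o, areas, min_area_km2 = 1), "zero observed")
  expect_equal(sc$n_units, 2L)           # a dropped by area, c by zero
  expect_equal(sc$n_dropped_area, 1L)
  expect_equal(sc$n_dropped_zero, 1L)
  expect_equal(sc$mare, 0)
  expect_error(suppressWarnings(mare(c(x = 1), c(x = 0))), "no reference")
  expect_error(mare(c(x = 1), c(y = 2)), "no matching")
})

test_that("cutoff selection minimizes MARE with ties to the smaller cutoff", {
  # grid of scores shaped like a division's cutoff scan
  scores <- c("1000" = 0.59, "1500" = 0.60, "2000" = 0.61,
              "2500" = 0.64, "3000" = 0.70)
  got <- select_cutoff_population(evaluator = function(v)
    scores[[as.character(v)]])
  expect_equal(got$cutoff, 1000)
  flat <- select_cutoff_population(evaluator = function(v) 0.5)
  expect_equal(flat$cutoff, 1000)  # tie rule
})

test_that("cutoff selection recovers the masking that generated the data", {
  # one county, four tracts; the low-population tract (1200 persons)
  # holds far less than its areal share, as when settlement avoids it
  spec <- grid_spec(4, 4)
  counties <- label_raster(spec, matrix(1, 4, 4), "county")
  tracts <- label_raster(spec, matrix(rep(1:4, each = 4), 4, 4), "tract")
  obs <- c("1" = 1200, "2" = 4000, "3" = 4400, "4" = 4800)
  census <- data.frame(unit_id = 1, decade = 2000,
                       population = sum(obs))
  elev <- value_raster(spec, matrix(10, 4, 4))
  ext <- label_raster(spec, matrix(0L, 4, 4), "urban")
  up <- data.frame(urban_id = integer(0), county = integer(0),
                   population = numeric(0))
  eval_cutoff <- function(cut) {
    w0 <- inhabitability_mask(
      elev, tract_labels = tracts, tract_populations = obs,
      config = inhabitability_config(cutoff_population = cut))
    res <- run_model("M3", 2000, counties, census, ext, up, w0 = w0)
    mare(zonal_sum(res$raster, tracts), obs)$mare
  }
  got <- select_cutoff_population(c(1000, 1500, 2000, 2500, 3000),
                                  evaluator = eval_cutoff)
  expect_equal(got$cutoff, 1500)
})

test_that("exponent calibration takes the grid argmin with ties downward", {
  expect_equal(calibrate_exponent("s", 0.7, function(v) 1)$value, 0.7)
  got <- calibrate_exponent("d", seq(0.2, 1, 0.2),
                            function(v) (v - 0.63)^2)
  expect_equal(got$value, 0.6)
  tie <- calibrate_exponent("s", c(0.5, 1, 2), function(v) 42)
  expect_equal(tie$value, 0.5)
})

test_that("model effectiveness is the consecutive MARE reduction", {
  m <- c(M1 = 6.96, M2 = 5.13, M3 = 1.55, M4 = 1.55, M5 = 1.54)
  d <- model_effectiveness(m)
  expect_equal(unname(round(d, 2)), c(1.83, 3.58, 0.00, 0.01))
  expect_named(d, c("M1-M2", "M2-M3", "M3-M4", "M4-M5"))
  expect_true(all(model_effectiveness(c(M1 = 2, M2 = 2, M3 = 2)) == 0))
  withr::with_seed(9, {
    v <- stats::setNames(stats::runif(5, 0.5, 8), paste0("M", 1:5))
  })
  expect_equal(unname(model_effectiveness(v)), -diff(unname(v)))
  # telescoping
  expect_equal(sum(model_effectiveness(v)), unname(v["M1"] - v["M5"]))
  expect_error(model_effectiveness(c(M1 = 1, M3 = 2)), "model gap")
})

test_that("validate_models scores the nested models on reference units", {
  w <- small_world()
  inp <- small_inputs()
  ref <- inp$tables$tract[inp$tables$tract$decade == 2000, ]
  refv <- stats::setNames(ref$population, ref$unit_id)
  rep <- validate_models(c("M1", "M2", "M3"), 2000, w$counties,
                         inp$tables$census,
                         extent_raster = inp$extents$extent_rasters[["2000"]],
                         urban_pops = urban_populations(w$registry, 2000),
                         w0 = inp$w0,
                         reference = refv, reference_labels = w$tracts)
  expect_equal(rep$table$model, c("M1", "M2", "M3"))
  expect_true(all(rep$table$mare >= 0))
  expect_length(rep$effectiveness, 2L)
  # urban/rural separation must help on an urban-concentrated world
  expect_lt(rep$table$mare[2], rep$table$mare[1])
})
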