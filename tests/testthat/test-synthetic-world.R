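test_that("world generation is deterministic given a seed", {
  cfg <- world_config(n_rows = 40, n_cols = 40, counties_per_division = 2,
                      decades = c(1990, 2000), seed = 7)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$truth[["2000"]]$data, w2$truth[["2000"]]$data)
  expect_identical(w1$elevation$data, w2$elevation$data)
  expect_identical(w1$registry$areas, w2$registry$areas)
  # and the generator does not disturb the session RNG stream
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(generate_world(cfg)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("noise-free footprints hit the scaling law pixel count exactly", {
  w <- exact_world()
  ca <- cell_area_km2(w$spec)
  for (k in seq_len(nrow(w$registry$areas))) {
    row <- w$registry$areas[k, ]
    expected <- floor(row$area_km2 / ca + 0.5)
    expect_equal(length(w$registry$footprints[[as.character(row$urban_id)]]),
                 max(1, expected))
    dv <- row$division
    expect_equal(row$area_km2,
                 w$truth_params$alpha[dv] * row$population^
                   w$truth_params$beta[dv],
                 tolerance = 1e-12)
  }
})

test_that("urban_fraction zero yields an all-rural world", {
  w <- generate_world(world_config(n_rows = 40, n_cols = 40,
                                   counties_per_division = 2,
                                   decades = c(1990, 2000),
                                   urban_fraction = 0, seed = 2))
  expect_equal(nrow(w$registry$areas), 0L)
  expect_true(all(w$extents[["2000"]]$data == 0L))
  tb <- world_to_census(w)
  expect_equal(nrow(tb$urban), 0L)
  expect_gt(sum(tb$census$population), 0)
})

test_that("derived census tables match a brute-force pixel scan", {
  w <- small_world()
  tb <- world_to_census(w)
  t <- "2000"
  truth <- w$truth[[t]]$data
  cen <- tb$census[tb$census$decade == 2000, ]
  for (ci in cen$unit_id) {
    expect_equal(cen$population[cen$unit_id == ci],
                 sum(truth[w$counties$data == ci]), tolerance = 1e-12)
  }
  # national conservation
  expect_equal(sum(cen$population), sum(truth, na.rm = TRUE),
               tolerance = 1e-12)
  # urban table equals sums over extent footprints
  urb <- tb$urban[tb$urban$decade == 2000, ]
  for (k in seq_len(nrow(urb))) {
    expect_equal(urb$population[k],
                 sum(truth[w$extents[[t]]$data == urb$urban_id[k]]),
                 tolerance = 1e-12)
  }
})

test_that("rural populations are feasible in every county and decade", {
  w <- small_world()
  tb <- world_to_census(w)
  for (t in unique(tb$census$decade)) {
    cen <- tb$census[tb$census$decade == t, ]
    urb <- merge(tb$urban[tb$urban$decade == t, ],
                 w$registry$areas[, c("urban_id", "county")],
                 by = "urban_id")
    for (ci in cen$unit_id) {
      p_u <- urb$population[urb$county == ci]
      expect_gte(rural_population(cen$population[cen$unit_id == ci], p_u,
                                  county = ci, decade = t), 0)
    }
  }
})

test_that("urban areas fall out of the registry below the census threshold", {
  w <- small_world()
  pops <- w$registry$populations
  expect_true(all(pops$population >= 2500))
  # early decades lose areas relative to the baseline
  n_by_decade <- table(pops$decade)
  expect_lte(n_by_decade[["1970"]], n_by_decade[["2000"]])
})

test_that("invalid world configurations are rejected", {
  expect_error(world_config(decades = c(2000, 1990)), "strictly increasing")
  expect_error(world_config(urban_fraction = 1.2), "fractions")
  expect_error(world_config(growth_rate = 0), "growth_rate")
  expect_error(world_config(baseline_decade = 1234), "baseline_decade")
  # urban disc that cannot fit: tiny counties, huge urban demand
  expect_error(
    generate_world(world_config(n_rows = 12, n_cols = 12,
                                counties_per_division = 6,
                                n_divisions = 1,
                                topo_intercept = log(5000),
                                decades = c(2000), seed = 1)),
    "urban|reduce")
})

test_that("ground truth follows the generative allocation form", {
  # independent recomputation of one county's truth from the stored
  # weight surfaces
  w <- small_world()
  t <- "2000"
  ci <- w$registry$areas$county[1]
  uid <- w$registry$areas$urban_id[1]
  sched <- w$truth_params$schedule
  ext <- w$extents[[t]]
  w2 <- build_w2(2000, ext, w$registry, w$truth_params$scaling,
                 w$counties, sched)
  s <- w$config$true_s; d <- w$config$true_d
  urban_px <- which(ext$data == uid)
  wgt <- w$w0$data[urban_px] * w$w1$data[urban_px]^s * w2$data[urban_px]^d
  p_u <- w$registry$populations
  p_u <- p_u$population[p_u$urban_id == uid & p_u$decade == 2000]
  expect_equal(w$truth[[t]]$data[urban_px], wgt / sum(wgt) * p_u,
               tolerance = 1e-10)
})
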