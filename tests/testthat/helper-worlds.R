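# Shared synthetic fixtures, generated once per test run and cached.

.world_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .world_cache)) {
    assign(key, force(expr), envir = .world_cache)
  }
  get(key, envir = .world_cache)
}

# small 4-decade world with urban areas, scaling noise on; the modest
# elevation span keeps every county populous enough to host an urban area,
# so both divisions have enough areas for a scaling fit
small_world <- function() {
  cached("small", generate_world(world_config(
    n_rows = 60, n_cols = 60, counties_per_division = 8,
    elevation_range = c(0, 1200),
    decades = seq(1970, 2000, 10), seed = 42)))
}

# same shape, noise-free scaling (exact extent recovery possible)
exact_world <- function() {
  cached("exact", generate_world(world_config(
    n_rows = 60, n_cols = 60, counties_per_division = 8,
    elevation_range = c(0, 1200),
    decades = seq(1970, 2000, 10), scaling_noise_sd = 0, seed = 42)))
}

small_inputs <- function() {
  cached("small_inputs", world_pipeline_inputs(small_world()))
}

# quick random raster pair for zonal oracles
random_zones <- function(nr, nc, n_zones, seed) {
  withr::with_seed(seed, {
    spec <- grid_spec(nr, nc)
    list(values = value_raster(spec, matrix(stats::runif(nr * nc), nr, nc)),
         zones = label_raster(spec, matrix(sample.int(n_zones, nr * nc,
                                                      replace = TRUE),
                                           nr, nc)),
         spec = spec)
  })
}
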