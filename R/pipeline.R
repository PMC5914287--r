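# End-to-end orchestration: simulate (or load) a world, fit the scaling
# law, reconstruct extents, build weight surfaces, allocate every model
# across the decade list, optionally calibrate the exponents, and validate
# against tract references. Outputs are written as Esri ASCII grids and
# CSVs with a JSON manifest recording parameters and content hashes so a
# rerun with the same configuration is verifiably identical.

#' Pipeline configuration
#'
#' @param out_dir Output directory (created if missing).
#' @param world A [world_config()] (a synthetic run), or `NULL` when all
#'   inputs are loaded from files via `paths`.
#' @param paths Named list of input file paths for a file-driven run:
#'   `counties`, `elevation`, `census`, … (synthetic runs ignore it).
#' @param models Models to allocate (default all of M1-M5).
#' @param decades Decades to map; defaults to the world's decade list.
#' @param skip_decades Decades excluded from mapping (e.g. a decade whose
#'   digital urban tables are missing).
#' @param calibrate Logical: grid-search (s, d) against tract references
#'   before allocation (otherwise `s`, `d` are used as given).
#' @param s,d Exponents used when `calibrate = FALSE`.
#' @param write_rasters Logical: write per-decade population grids.
#' @param log_level `"info"` or `"quiet"`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, world = world_config(),
                            paths = list(), models = MODEL_NAMES,
                            decades = NULL, skip_decades = integer(0),
                            calibrate = FALSE, s = 1, d = 1,
                            write_rasters = TRUE, log_level = "info") {
  structure(list(out_dir = out_dir, world = world, paths = paths,
                 models = match.arg(models, MODEL_NAMES,
                                    several.ok = TRUE),
                 decades = decades, skip_decades = skip_decades,
                 calibrate = calibrate, s = s, d = d,
                 write_rasters = write_rasters, log_level = log_level),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `world`
#' key holds [world_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config error: no such file '", path, "'",
                               call. = FALSE)
  y <- yaml::read_yaml(path)
  wc <- if (is.null(y$world)) world_config() else
    do.call(world_config, y$world)
  args <- y[setdiff(names(y), "world")]
  args$world <- wc
  do.call(pipeline_config, args)
}

pipe_log <- function(cfg, stage, msg) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  msg))
}

run_stage <- function(cfg, stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(force(expr), error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  pipe_log(cfg, stage, sprintf("done in %.2f s",
                               proc.time()[["elapsed"]] - t0))
  out
}

#' Fit the downscaling pipeline's inputs on a synthetic world
#'
#' Runs every estimation stage the allocation models depend on: census
#' tables from the world's ground truth, per-division scaling fits on the
#' baseline urban registry, per-decade extent reconstruction, the
#' inhabitability mask, regional topographic fits (county density over
#' inhabitable area vs mean elevation at the baseline decade), and the
#' per-decade socioeconomic weight surfaces.
#'
#' @param world A `synthetic_world`.
#' @param decades Decades to prepare (default: the world's).
#' @param baseline Baseline decade (default: the world's).
#' @return List: `tables`, `scaling`, `extents`, `w0`, `w1`, `w2`
#'   (named list by decade), `topo_fits`. `scaling`, `extents` and `w2`
#'   are `NULL` for worlds without urban areas.
#' @export
world_pipeline_inputs <- function(world,
                                  decades = world$config$decades,
                                  baseline = world$config$baseline_decade) {
  stopifnot(inherits(world, "synthetic_world"))
  spec <- world$spec
  tables <- world_to_census(world)
  scaling <- if (nrow(world$registry$areas) > 0) {
    fit_scaling_by_division(world$registry$areas)
  } else NULL
  extents <- if (!is.null(scaling)) {
    delineate_registry(world$registry, scaling, decades, spec,
                       baseline_decade = baseline)
  } else NULL
  w0 <- world$w0
  cen <- tables$census[tables$census$decade == baseline, ]
  inh <- zonal_sum(w0, world$counties) * cell_area_km2(spec)
  mz <- zonal_mean(world$elevation, world$counties)
  dens <- stats::setNames(
    cen$population / as.numeric(inh[as.character(cen$unit_id)]),
    cen$unit_id)
  topo_fits <- lapply(sort(unique(world$config$region_of_division)),
                      function(rg) {
    sel <- world$regions$data == rg & world$counties$data != 0L
    cids <- as.character(sort(unique(world$counties$data[sel])))
    fit_topo_relation(as.numeric(dens[cids]), as.numeric(mz[cids]),
                      region = rg)
  })
  w1 <- topo_weight(world$elevation, topo_fits, world$regions)
  w2 <- if (!is.null(extents)) {
    sched <- travel_schedule(world$config$travel_anchors)
    stats::setNames(lapply(decades, function(t) {
      build_w2(t, extents$extent_rasters[[as.character(t)]],
               world$registry, scaling, world$counties, sched)
    }), decades)
  } else NULL
  list(tables = tables, scaling = scaling, extents = extents,
       w0 = w0, w1 = w1, w2 = w2, topo_fits = topo_fits)
}

#' Run the full downscaling pipeline
#'
#' Stages: simulate the world, derive census tables, fit per-division
#' scaling, reconstruct per-decade extents, build the weight surfaces,
#' (optionally) calibrate the exponents, allocate every requested model
#' over the decade list, validate against tract references for the
#' baseline decade, and write a manifest.
#'
#' @param config A [pipeline_config()] or path to its YAML file.
#' @return The manifest (list), invisibly written as
#'   `manifest.json` in `out_dir`: inputs, parameters, output files with
#'   md5 hashes, per-stage products.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  world <- run_stage(config, "simulate", generate_world(config$world))
  spec <- world$spec
  decades <- if (is.null(config$decades)) config$world$decades else
    config$decades
  decades <- setdiff(decades, config$skip_decades)
  baseline <- config$world$baseline_decade

  wts <- run_stage(config, "fit",
                   world_pipeline_inputs(world, decades, baseline))
  tables <- wts$tables
  scaling <- wts$scaling
  extents <- wts$extents

  tract_ref <- tables$tract[tables$tract$decade == baseline, ]
  reference <- stats::setNames(tract_ref$population, tract_ref$unit_id)

  if (config$calibrate && !is.null(extents)) {
    cal <- run_stage(config, "calibrate", {
      up <- urban_populations(world$registry, baseline)
      calibrate_model_exponents(
        baseline, world$counties, tables$census,
        extents$extent_rasters[[as.character(baseline)]], up,
        wts$w0, wts$w1, wts$w2[[as.character(baseline)]],
        reference, world$tracts)
    })
    s_use <- cal$s; d_use <- cal$d
  } else {
    cal <- NULL
    s_use <- config$s; d_use <- config$d
  }

  results <- run_stage(config, "allocate", {
    out <- list()
    for (mo in config$models) {
      out[[mo]] <- run_history(
        mo, decades, world$counties, tables$census,
        extent_rasters = if (!is.null(extents)) extents$extent_rasters,
        registry = world$registry, w0 = wts$w0, w1 = wts$w1, w2 = wts$w2,
        s = s_use, d = d_use)
    }
    out
  })

  report <- run_stage(config, "validate", {
    up <- if (!is.null(extents)) urban_populations(world$registry,
                                                   baseline)
    validate_models(config$models, baseline, world$counties,
                    tables$census,
                    extent_raster = if (!is.null(extents))
                      extents$extent_rasters[[as.character(baseline)]],
                    urban_pops = up, w0 = wts$w0, w1 = wts$w1,
                    w2 = if (!is.null(wts$w2))
                      wts$w2[[as.character(baseline)]],
                    s = s_use, d = d_use,
                    reference = reference,
                    reference_labels = world$tracts)
  })

  files <- character(0)
  if (config$write_rasters) {
    for (mo in names(results)) {
      for (t in names(results[[mo]])) {
        f <- file.path(config$out_dir, sprintf("pop_%s_%s.asc", mo, t))
        write_raster(results[[mo]][[t]]$raster, f)
        # conservation audit on the written product
        back <- read_raster(f, "value", spec = spec)
        cs <- zonal_sum(back, world$counties)
        cen <- tables$census[tables$census$decade == as.integer(t), ]
        obs <- stats::setNames(cen$population, cen$unit_id)
        rel <- abs(cs[names(obs)] - obs) / pmax(obs, 1)
        if (any(rel > 1e-6)) {
          stop("data inconsistency: written raster ", f,
               " violates county conservation", call. = FALSE)
        }
        files <- c(files, f)
      }
    }
  }
  cf <- file.path(config$out_dir, "census_counties.csv")
  write_census_table(tables$census, cf)
  files <- c(files, cf)
  if (!is.null(scaling)) {
    sf <- file.path(config$out_dir, "scaling.csv")
    utils::write.csv(scaling, sf, row.names = FALSE)
    files <- c(files, sf)
  }

  manifest <- list(
    manifest_version = 1L,
    seed = config$world$seed,
    parameters = list(models = config$models, decades = decades,
                      baseline_decade = baseline, s = s_use, d = d_use,
                      calibrated = config$calibrate),
    scaling = if (!is.null(scaling)) scaling,
    calibration = if (!is.null(cal)) cal[c("s", "d")],
    validation = list(table = report$table,
                      effectiveness = as.list(report$effectiveness)),
    outputs = lapply(stats::setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
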