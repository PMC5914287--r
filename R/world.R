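# Synthetic study regions with known ground truth. The generator builds a
# planar world that satisfies, by construction, every statistical
# assumption the downscaling pipeline relies on: counties tile the grid as
# rectangular blocks, urban footprints are single-county discs sized from
# the area-population power law, county densities follow the regional
# log-density / elevation relation, population trajectories are exponential
# in time, and per-pixel ground-truth populations are drawn from the full
# weighted-allocation generative form with known exponents. Fitting the
# pipeline to such a world is therefore a well-posed parameter-recovery
# problem.

#' Configuration for a synthetic world
#'
#' Defaults describe a modest two-division study region whose statistical
#' conditions mirror the study design: scaling factor 0.95 in all divisions
#' except the last ("Pacific-like") division at 0.86, about 80% of county
#' population urban, a long-run growth factor of 1.23 per decade, decadal
#' censuses 1790-2010, and a travel range rising from 30 km to 100 km.
#'
#' @param n_rows,n_cols,cell_size_km Grid shape (default 100 x 100 at 1 km).
#' @param n_divisions Number of census divisions (vertical strips).
#' @param counties_per_division Counties per division (horizontal bands).
#' @param tracts_per_county Census tracts per county (vertical slices).
#' @param subdivisions_per_county County subdivisions per county.
#' @param decades Strictly increasing decade list.
#' @param baseline_decade Decade with observed urban footprints (default
#'   the last decade).
#' @param true_beta_by_division Scaling factors; default 0.95 everywhere
#'   with 0.86 in the last division when there are at least two.
#' @param true_alpha_by_division Proportionality coefficients
#'   (km^2 persons^-beta), recycled.
#' @param scaling_noise_sd Lognormal scatter (sd of log10 area) around the
#'   scaling law.
#' @param region_of_division Region id per division (default: one region
#'   per division).
#' @param true_m_by_region Density-elevation slopes (1/m) per region.
#' @param topo_intercept ln(persons/km^2) at sea level.
#' @param topo_noise_sd SD of the ln-density county noise.
#' @param unweighted_regions Region ids whose topography is flagged
#'   unweighted in the ground truth (an R0-like case); default none.
#' @param elevation_range County base-elevation range in m.
#' @param elevation_gradient_m Max within-county elevation tilt (m).
#' @param elevation_noise_sd_m Per-pixel elevation roughness (m).
#' @param urban_fraction Fraction of a county's population in its urban
#'   area at any decade (0 disables urban areas).
#' @param min_urban_population Census urban threshold (default 2500).
#' @param growth_rate Per-decade multiplicative population growth.
#' @param water_fraction,protected_fraction Area fractions masked out.
#' @param true_s,true_d Ground-truth weighting exponents.
#' @param travel_anchors Travel-range anchors (see [travel_schedule()]).
#' @param seed Integer seed; all randomness flows from it.
#' @return Object of class `world_config`.
#' @export
world_config <- function(n_rows = 100, n_cols = 100, cell_size_km = 1,
                         n_divisions = 2, counties_per_division = 8,
                         tracts_per_county = 4,
                         subdivisions_per_county = 2,
                         decades = seq(1790, 2010, by = 10),
                         baseline_decade = max(decades),
                         true_beta_by_division = NULL,
                         true_alpha_by_division = 0.002,
                         scaling_noise_sd = 0.05,
                         region_of_division = seq_len(n_divisions),
                         true_m_by_region = -0.001,
                         topo_intercept = log(50),
                         topo_noise_sd = 0.3,
                         unweighted_regions = integer(0),
                         elevation_range = c(0, 2500),
                         elevation_gradient_m = 150,
                         elevation_noise_sd_m = 20,
                         urban_fraction = 0.8,
                         min_urban_population = 2500,
                         growth_rate = 1.23,
                         water_fraction = 0.05,
                         protected_fraction = 0.05,
                         true_s = 1.0, true_d = 0.6,
                         travel_anchors = c("1790" = 30, "2000" = 100),
                         seed = 1L) {
  if (is.null(true_beta_by_division)) {
    true_beta_by_division <- rep(0.95, n_divisions)
    if (n_divisions >= 2) true_beta_by_division[n_divisions] <- 0.86
  }
  cfg <- list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    cell_size_km = cell_size_km, n_divisions = as.integer(n_divisions),
    counties_per_division = as.integer(counties_per_division),
    tracts_per_county = as.integer(tracts_per_county),
    subdivisions_per_county = as.integer(subdivisions_per_county),
    decades = as.integer(decades),
    baseline_decade = as.integer(baseline_decade),
    true_beta_by_division = rep_len(true_beta_by_division, n_divisions),
    true_alpha_by_division = rep_len(true_alpha_by_division, n_divisions),
    scaling_noise_sd = scaling_noise_sd,
    region_of_division = as.integer(rep_len(region_of_division,
                                            n_divisions)),
    true_m_by_region = true_m_by_region,
    topo_intercept = topo_intercept, topo_noise_sd = topo_noise_sd,
    unweighted_regions = as.integer(unweighted_regions),
    elevation_range = elevation_range,
    elevation_gradient_m = elevation_gradient_m,
    elevation_noise_sd_m = elevation_noise_sd_m,
    urban_fraction = urban_fraction,
    min_urban_population = min_urban_population,
    growth_rate = growth_rate,
    water_fraction = water_fraction,
    protected_fraction = protected_fraction,
    true_s = true_s, true_d = true_d,
    travel_anchors = travel_anchors, seed = as.integer(seed))
  n_regions <- max(cfg$region_of_division)
  cfg$true_m_by_region <- rep_len(cfg$true_m_by_region, n_regions)
  validate_world_config(cfg)
  structure(cfg, class = "world_config")
}

validate_world_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_rows >= 1, n_cols >= 1, cell_size_km > 0,
              n_divisions >= 1, counties_per_division >= 1,
              tracts_per_county >= 1, subdivisions_per_county >= 1)
    if (is.unsorted(decades, strictly = TRUE)) {
      stop("config error: decades must be strictly increasing",
           call. = FALSE)
    }
    if (!baseline_decade %in% decades) {
      stop("config error: baseline_decade must be one of the decades",
           call. = FALSE)
    }
    if (any(c(urban_fraction, water_fraction, protected_fraction) < 0) ||
        any(c(urban_fraction, water_fraction, protected_fraction) > 1)) {
      stop("config error: fractions must lie in [0, 1]", call. = FALSE)
    }
    stopifnot(all(true_beta_by_division > 0),
              all(true_alpha_by_division > 0),
              growth_rate > 0, scaling_noise_sd >= 0,
              true_s >= 0, true_d >= 0)
  })
  invisible(cfg)
}

# contiguous near-equal partition of 1..n into k pieces; returns piece id
# per index
split_index <- function(n, k) {
  sizes <- rep(n %/% k, k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  rep(seq_len(k), times = sizes)
}

#' Generate a synthetic world
#'
#' See [world_config()] for the generative model. The result carries every
#' raster and table the pipeline consumes, plus the ground truth the
#' pipeline is supposed to recover: per-decade per-pixel population, true
#' urban extents, and the true parameter values.
#'
#' @param config A [world_config()].
#' @return Object of class `synthetic_world`: `spec`, label rasters
#'   (`counties`, `tracts`, `subdivisions`, `divisions`, `regions`),
#'   `elevation`, `water`, `protected`, `w0`, `w1`, `registry`
#'   (an [urban_registry()]), `truth` (per-decade `value_raster`s),
#'   `extents` (per-decade urban `label_raster`s), `census` (county
#'   table), `config`, and `truth_params`.
#' @export
generate_world <- function(config = world_config()) {
  validate_world_config(config)
  withr::with_seed(config$seed, generate_world_impl(config))
}

generate_world_impl <- function(cfg) {
  spec <- grid_spec(cfg$n_rows, cfg$n_cols, cfg$cell_size_km)
  nr <- cfg$n_rows; nc <- cfg$n_cols
  ca <- cell_area_km2(spec)
  n_div <- cfg$n_divisions
  cpd <- cfg$counties_per_division
  n_county <- n_div * cpd

  ## --- administrative partitions -------------------------------------
  div_of_col <- split_index(nc, n_div)
  band_of_row <- split_index(nr, cpd)
  div_m <- matrix(div_of_col[col(matrix(0, nr, nc))], nr, nc)
  county_m <- matrix(0L, nr, nc)
  for (d in seq_len(n_div)) {
    cols <- which(div_of_col == d)
    county_m[, cols] <- (d - 1L) * cpd + band_of_row
  }
  reg_m <- matrix(cfg$region_of_division[div_m], nr, nc)
  tract_m <- matrix(0L, nr, nc)
  subdiv_m <- matrix(0L, nr, nc)
  county_cols <- list(); county_rows <- list()
  for (d in seq_len(n_div)) {
    cols <- which(div_of_col == d)
    slice_t <- split_index(length(cols), cfg$tracts_per_county)
    slice_s <- split_index(length(cols), cfg$subdivisions_per_county)
    for (b in seq_len(cpd)) {
      ci <- (d - 1L) * cpd + b
      rows <- which(band_of_row == b)
      county_rows[[ci]] <- rows
      county_cols[[ci]] <- cols
      tract_m[rows, cols] <- (ci - 1L) * cfg$tracts_per_county +
        rep(slice_t, each = length(rows))
      subdiv_m[rows, cols] <- (ci - 1L) * cfg$subdivisions_per_county +
        rep(slice_s, each = length(rows))
    }
  }
  div_of_county <- rep(seq_len(n_div), each = cpd)
  reg_of_county <- cfg$region_of_division[div_of_county]

  ## --- elevation -----------------------------------------------------
  base_z <- stats::runif(n_county, cfg$elevation_range[1],
                         cfg$elevation_range[2])
  tilt_r <- stats::runif(n_county, -1, 1) * cfg$elevation_gradient_m
  tilt_c <- stats::runif(n_county, -1, 1) * cfg$elevation_gradient_m
  elev <- matrix(0, nr, nc)
  for (ci in seq_len(n_county)) {
    rows <- county_rows[[ci]]; cols <- county_cols[[ci]]
    rmid <- mean(rows); cmid <- mean(cols)
    rg <- outer((rows - rmid) / max(1, diff(range(rows))),
                rep(1, length(cols))) * tilt_r[ci]
    cg <- outer(rep(1, length(rows)),
                (cols - cmid) / max(1, diff(range(cols)))) * tilt_c[ci]
    elev[rows, cols] <- base_z[ci] + rg + cg
  }
  elev <- elev + matrix(stats::rnorm(nr * nc, 0, cfg$elevation_noise_sd_m),
                        nr, nc)
  elev <- pmax(elev, 0)

  ## --- urban centers and mask reserve --------------------------------
  center_of <- lapply(seq_len(n_county), function(ci) {
    c(row = as.integer(round(mean(county_rows[[ci]]))),
      col = as.integer(round(mean(county_cols[[ci]]))))
  })
  r_res <- vapply(seq_len(n_county), function(ci) {
    min(length(county_rows[[ci]]), length(county_cols[[ci]])) / 2 - 0.5
  }, numeric(1))
  reserved <- matrix(FALSE, nr, nc)
  if (cfg$urban_fraction > 0) {
    rr <- row(reserved); cc <- col(reserved)
    for (ci in seq_len(n_county)) {
      cen <- center_of[[ci]]
      reserved <- reserved |
        ((rr - cen["row"])^2 + (cc - cen["col"])^2 <= r_res[ci]^2)
    }
  }

  ## --- water / protected masks ---------------------------------------
  draw_mask <- function(frac, occupied) {
    m <- matrix(FALSE, nr, nc)
    target <- round(frac * nr * nc)
    if (target == 0) return(m)
    free <- which(!reserved & !occupied)
    seeds <- sample(free, min(length(free), target))
    n_put <- 0L
    for (p in seeds) {
      if (n_put >= target) break
      if (m[p]) next
      patch <- p
      # grow a small rectangular patch (1-2 cells each way)
      pr <- ((p - 1L) %% nr) + 1L; pc <- ((p - 1L) %/% nr) + 1L
      dr <- sample(0:1, 1); dc <- sample(0:1, 1)
      for (r2 in pr:min(nr, pr + dr)) for (c2 in pc:min(nc, pc + dc)) {
        q <- (c2 - 1L) * nr + r2
        if (!reserved[q] && !occupied[q] && !m[q]) patch <- c(patch, q)
      }
      patch <- unique(patch)
      m[patch] <- TRUE
      n_put <- n_put + length(patch)
    }
    m
  }
  water <- draw_mask(cfg$water_fraction, matrix(FALSE, nr, nc))
  protected <- draw_mask(cfg$protected_fraction, water)

  elevation <- value_raster(spec, elev, name = "elevation_m")
  water_r <- label_raster(spec, water * 1L, level = "water")
  prot_r <- label_raster(spec, protected * 1L, level = "protected")
  counties <- label_raster(spec, county_m, level = "county")
  divisions <- label_raster(spec, div_m, level = "division")
  regions <- label_raster(spec, reg_m, level = "region")
  tracts <- label_raster(spec, tract_m, level = "tract")
  subdivs <- label_raster(spec, subdiv_m, level = "subdivision")

  w0 <- inhabitability_mask(elevation, water_r, prot_r,
                            config = inhabitability_config())

  ## --- county populations from the density-elevation relation --------
  inh_area <- zonal_sum(w0, counties) * ca  # w0 is 0/1: sum counts pixels
  mean_z <- zonal_mean(elevation, counties)
  eps <- stats::rnorm(n_county, 0, cfg$topo_noise_sd)
  m_true <- cfg$true_m_by_region[reg_of_county]
  pd <- exp(m_true * as.numeric(mean_z[as.character(seq_len(n_county))]) +
              cfg$topo_intercept + eps)
  p_t_base <- pd * as.numeric(inh_area[as.character(seq_len(n_county))])

  ## --- urban registry -------------------------------------------------
  betas <- cfg$true_beta_by_division
  alphas <- cfg$true_alpha_by_division
  areas_rows <- list(); pop_rows <- list()
  footprints <- list(); centers <- list(); ordered <- list()
  noise_mult <- 10^stats::rnorm(n_county, 0, cfg$scaling_noise_sd)
  growth_exp <- function(t) {
    cfg$growth_rate^((t - cfg$baseline_decade) / 10)
  }
  if (cfg$urban_fraction > 0) {
    for (ci in seq_len(n_county)) {
      p_u_base <- cfg$urban_fraction * p_t_base[ci]
      if (p_u_base < cfg$min_urban_population) next
      dv <- div_of_county[ci]
      a_base <- alphas[dv] * p_u_base^betas[dv] * noise_mult[ci]
      n_base <- max(1L, as.integer(round_half_up(a_base / ca)))
      county_px <- which(county_m == ci)
      cen <- center_of[[ci]]
      ord <- order_footprint(county_px, cen, spec)
      if (n_base > length(ord)) {
        stop("config error: urban footprint (", n_base,
             " px) exceeds county ", ci,
             "; reduce urban_fraction or enlarge counties", call. = FALSE)
      }
      fp <- ord[seq_len(n_base)]
      d_last <- pixel_distance(fp[n_base], cen, spec)
      if (d_last > r_res[ci] * spec$cell_size_km) {
        stop("config error: urban disc in county ", ci,
             " does not fit the mask-free reserve; reduce urban_fraction",
             call. = FALSE)
      }
      uid <- ci  # one urban area per county: id = county id
      footprints[[as.character(uid)]] <- fp
      ordered[[as.character(uid)]] <- ord
      centers[[as.character(uid)]] <- cen
      areas_rows[[length(areas_rows) + 1L]] <- data.frame(
        urban_id = uid, division = dv, county = ci,
        area_km2 = a_base, population = p_u_base)
      for (t in cfg$decades) {
        p_u_t <- p_u_base * growth_exp(t)
        if (p_u_t >= cfg$min_urban_population) {
          pop_rows[[length(pop_rows) + 1L]] <- data.frame(
            urban_id = uid, decade = t, population = p_u_t)
        }
      }
    }
  }
  empty_areas <- data.frame(urban_id = integer(0), division = integer(0),
                            county = integer(0), area_km2 = numeric(0),
                            population = numeric(0))
  empty_pops <- data.frame(urban_id = integer(0), decade = integer(0),
                           population = numeric(0))
  registry <- urban_registry(
    if (length(areas_rows)) do.call(rbind, areas_rows) else empty_areas,
    if (length(pop_rows)) do.call(rbind, pop_rows) else empty_pops,
    footprints, centers, min_population = cfg$min_urban_population)

  ## --- true weight surfaces ------------------------------------------
  topo_fits <- lapply(sort(unique(reg_of_county)), function(rg) {
    structure(list(region = rg, m = cfg$true_m_by_region[rg],
                   b = cfg$topo_intercept, p_value = 0,
                   weighted = !(rg %in% cfg$unweighted_regions),
                   n_fit = sum(reg_of_county == rg), band = NULL),
              class = "region_topo_fit")
  })
  w1 <- topo_weight(elevation, topo_fits, regions)
  true_scaling <- data.frame(division = seq_len(n_div), alpha = alphas,
                             beta = betas, lambda = 2 - 2 * betas)
  schedule <- travel_schedule(cfg$travel_anchors)

  ## --- per-decade truth -----------------------------------------------
  truth <- list(); extents <- list()
  s <- cfg$true_s; d <- cfg$true_d
  for (t in cfg$decades) {
    key <- as.character(t)
    ext_m <- matrix(0L, nr, nc)
    live <- registry$populations[registry$populations$decade == t, ]
    n_t_of <- stats::setNames(integer(0), character(0))
    for (k in seq_len(nrow(live))) {
      uid <- live$urban_id[k]
      dv <- div_of_county[uid]
      a_t <- alphas[dv] * live$population[k]^betas[dv] * noise_mult[uid]
      n_t <- min(max(1L, as.integer(round_half_up(a_t / ca))),
                 length(footprints[[as.character(uid)]]))
      ext_m[footprints[[as.character(uid)]][seq_len(n_t)]] <- uid
      n_t_of[as.character(uid)] <- n_t
    }
    ext_r <- label_raster(spec, ext_m, level = "urban")
    w2 <- build_w2(t, ext_r, registry, true_scaling, counties, schedule)
    pop <- matrix(NA_real_, nr, nc)
    pop[county_m != 0L] <- 0
    for (ci in seq_len(n_county)) {
      p_t_i <- p_t_base[ci] * growth_exp(t)
      county_px <- which(county_m == ci)
      live_i <- live[live$urban_id == ci, ]
      urban_px <- integer(0)
      if (nrow(live_i) == 1L) {
        urban_px <- footprints[[as.character(ci)]][
          seq_len(n_t_of[[as.character(ci)]])]
        w <- w0$data[urban_px] * w1$data[urban_px]^s * w2$data[urban_px]^d
        tot <- sum(w)
        pop[urban_px] <- if (tot > 0) w / tot * live_i$population else
          live_i$population / length(urban_px)
      }
      rural_px <- setdiff(county_px, urban_px)
      p_r <- p_t_i - sum(live_i$population)
      w <- w0$data[rural_px] * w1$data[rural_px]^s * w2$data[rural_px]^d
      tot <- sum(w)
      pop[rural_px] <- if (tot > 0) w / tot * p_r else p_r / length(rural_px)
    }
    truth[[key]] <- value_raster(spec, pop,
                                 name = sprintf("truth_population_%s", t))
    extents[[key]] <- ext_r
  }

  ## --- derived census table -------------------------------------------
  cen_rows <- lapply(cfg$decades, function(t) {
    s_t <- zonal_sum(truth[[as.character(t)]], counties)
    data.frame(unit_id = as.integer(names(s_t)), decade = t,
               population = as.numeric(s_t),
               area_km2 = as.numeric(table(county_m[county_m != 0L])[
                 names(s_t)]) * ca)
  })
  census <- do.call(rbind, cen_rows)

  structure(
    list(spec = spec, counties = counties, tracts = tracts,
         subdivisions = subdivs, divisions = divisions, regions = regions,
         elevation = elevation, water = water_r, protected = prot_r,
         w0 = w0, w1 = w1, registry = registry, truth = truth,
         extents = extents, census = census, config = cfg,
         truth_params = list(alpha = alphas, beta = betas,
                             lambda = 2 - 2 * betas,
                             m = cfg$true_m_by_region,
                             b = cfg$topo_intercept,
                             s = s, d = d, schedule = schedule,
                             topo_fits = topo_fits,
                             scaling = true_scaling)),
    class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> %d x %d km, %d counties in %d divisions, %d urban areas, %d decades\n",
    x$spec$n_rows, x$spec$n_cols,
    x$config$n_divisions * x$config$counties_per_division,
    x$config$n_divisions, nrow(x$registry$areas),
    length(x$config$decades)))
  invisible(x)
}

#' Derive census tables from a synthetic world's ground truth
#'
#' All tables are zonal sums of the per-decade truth rasters, so the
#' county table conserves the ground truth exactly and the tract /
#' subdivision tables provide validation references.
#'
#' @param world A `synthetic_world`.
#' @return List: `census` (county `unit_id`, `decade`, `population`,
#'   `area_km2`), `urban` (`urban_id`, `decade`, `population`), `tract`
#'   and `subdivision` (same columns as `census`, no area for urban).
#' @export
world_to_census <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  ca <- cell_area_km2(world$spec)
  per_level <- function(zones) {
    za <- zone_areas(zones)
    rows <- lapply(names(world$truth), function(key) {
      s_t <- zonal_sum(world$truth[[key]], zones)
      data.frame(unit_id = as.integer(names(s_t)),
                 decade = as.integer(key),
                 population = as.numeric(s_t),
                 area_km2 = za$area_km2[match(as.integer(names(s_t)),
                                              za$zone)])
    })
    do.call(rbind, rows)
  }
  urban_rows <- lapply(names(world$truth), function(key) {
    ext <- world$extents[[key]]
    if (all(ext$data == 0L)) return(NULL)
    s_t <- zonal_sum(world$truth[[key]], ext)
    data.frame(urban_id = as.integer(names(s_t)),
               decade = as.integer(key), population = as.numeric(s_t))
  })
  urban_rows <- Filter(Negate(is.null), urban_rows)
  list(census = per_level(world$counties),
       urban = if (length(urban_rows)) do.call(rbind, urban_rows) else
         data.frame(urban_id = integer(0), decade = integer(0),
                    population = numeric(0)),
       tract = per_level(world$tracts),
       subdivision = per_level(world$subdivisions))
}

#' Simulate (area, population) pairs from the urban scaling law
#'
#' Stand-alone generator for scaling-fit experiments: populations are
#' drawn log-uniformly between `pop_range` and areas follow
#' `alpha * P^beta` with lognormal scatter of sd `log10_noise_sd` in
#' log10 area.
#'
#' @param n Number of urban areas.
#' @param alpha,beta Scaling-law parameters.
#' @param log10_noise_sd Lognormal noise sd (log10 units).
#' @param pop_range Population range (default 2500 to 1e6).
#' @param seed Optional seed.
#' @return data.frame `population`, `area_km2`.
#' @export
simulate_urban_scaling <- function(n, alpha = 0.002, beta = 0.95,
                                   log10_noise_sd = 0.05,
                                   pop_range = c(2500, 1e6),
                                   seed = NULL) {
  gen <- function() {
    p <- 10^stats::runif(n, log10(pop_range[1]), log10(pop_range[2]))
    a <- alpha * p^beta * 10^stats::rnorm(n, 0, log10_noise_sd)
    data.frame(population = p, area_km2 = a)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate county densities from the regional density-elevation relation
#'
#' @param n Number of counties.
#' @param m Slope (1/m) of `ln(density)` on elevation.
#' @param b Intercept (ln persons/km^2).
#' @param noise_sd SD of the ln-density noise.
#' @param z_range County mean-elevation range (m).
#' @param seed Optional seed.
#' @return data.frame `mean_elevation_m`, `density_per_km2`.
#' @export
simulate_county_topo <- function(n, m = -0.001, b = log(50),
                                 noise_sd = 0.3, z_range = c(0, 2500),
                                 seed = NULL) {
  gen <- function() {
    z <- stats::runif(n, z_range[1], z_range[2])
    d <- exp(m * z + b + stats::rnorm(n, 0, noise_sd))
    data.frame(mean_elevation_m = z, density_per_km2 = d)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
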