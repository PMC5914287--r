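# Influence-coefficient grids. Three per-pixel weights drive allocation:
#   w0  binary inhabitability (water, protected, highland, low-pop tracts)
#   w1  topographic suitability exp(m * z) from regional density-elevation
#       regressions, constant over time
#   w2  socioeconomic desirability: inverse-power distance decay inside
#       urban areas, gravity-model market potential for rural pixels;
#       changes each decade with the urban system and the travel range.

#' Inhabitability configuration
#'
#' @param elevation_max_m Pixels above this elevation are non-inhabitable
#'   (default 3500 m).
#' @param min_water_patch_km2 Water patches at least this large are
#'   non-inhabitable (default 1 km^2).
#' @param cutoff_population Tract population below which a tract is treated
#'   as non-inhabitable. Scalar, or named vector by division (in which case
#'   a division raster must be supplied to [inhabitability_mask()]).
#'   Default 0 (no tract masking).
#' @return List of class `inhabitability_config`.
#' @export
inhabitability_config <- function(elevation_max_m = 3500,
                                  min_water_patch_km2 = 1,
                                  cutoff_population = 0) {
  stopifnot(elevation_max_m > 0, min_water_patch_km2 > 0,
            all(cutoff_population >= 0))
  structure(list(elevation_max_m = elevation_max_m,
                 min_water_patch_km2 = min_water_patch_km2,
                 cutoff_population = cutoff_population),
            class = "inhabitability_config")
}

#' Binary inhabitability weight w0
#'
#' A pixel is non-inhabitable (w0 = 0) when it is protected, belongs to a
#' water patch of at least `min_water_patch_km2`, lies above
#' `elevation_max_m`, or falls in a census tract whose population is below
#' the division's cutoff. Everything else gets w0 = 1. The mask is built
#' once from the calibration decade's tract table and held constant over
#' time.
#'
#' @param elevation `value_raster` of elevation (m).
#' @param water_mask,protected_mask `label_raster`s or 0/1 `value_raster`s
#'   (nonzero = water / protected); either may be `NULL`.
#' @param tract_labels Optional `label_raster` of census tracts.
#' @param tract_populations Optional named numeric vector (or data.frame
#'   with `unit_id`, `population`) of tract populations for the calibration
#'   decade.
#' @param config An [inhabitability_config()].
#' @param division_labels Optional `label_raster` of divisions, needed when
#'   `config$cutoff_population` is a per-division vector.
#' @return A `value_raster` of 0/1 weights.
#' @export
inhabitability_mask <- function(elevation, water_mask = NULL,
                                protected_mask = NULL,
                                tract_labels = NULL,
                                tract_populations = NULL,
                                config = inhabitability_config(),
                                division_labels = NULL) {
  check_aligned(elevation, water_mask, protected_mask, tract_labels,
                division_labels)
  spec <- elevation$spec
  w0 <- matrix(1, spec$n_rows, spec$n_cols)
  w0[!is.na(elevation$data) & elevation$data > config$elevation_max_m] <- 0

  if (!is.null(water_mask)) {
    wet <- water_mask$data != 0 & !is.na(water_mask$data)
    min_px <- ceiling(config$min_water_patch_km2 / cell_area_km2(spec))
    if (min_px <= 1L) {
      w0[wet] <- 0
    } else {
      comp <- connected_components(wet)
      sizes <- tabulate(comp)
      big <- matrix(FALSE, spec$n_rows, spec$n_cols)
      big[wet] <- sizes[comp[wet]] >= min_px
      w0[big] <- 0
    }
  }
  if (!is.null(protected_mask)) {
    w0[protected_mask$data != 0 & !is.na(protected_mask$data)] <- 0
  }

  cutoff <- config$cutoff_population
  if (!is.null(tract_labels) && !is.null(tract_populations) &&
      any(cutoff > 0)) {
    if (is.data.frame(tract_populations)) {
      tract_populations <- stats::setNames(tract_populations$population,
                                           tract_populations$unit_id)
    }
    tl <- tract_labels$data
    pop <- tract_populations[as.character(tl)]
    pop[tl == 0L] <- NA
    if (length(cutoff) > 1L) {
      if (is.null(division_labels)) {
        stop("per-division cutoffs require division_labels", call. = FALSE)
      }
      cut_px <- cutoff[as.character(division_labels$data)]
    } else {
      cut_px <- rep(cutoff, length(tl))
    }
    sel <- !is.na(pop) & !is.na(cut_px) & pop < cut_px
    w0[sel] <- 0
  }
  w0[is.na(elevation$data)] <- NA
  value_raster(spec, w0, name = "w0_inhabitability")
}

#' Fit the regional density-elevation relation
#'
#' OLS of `ln(density)` on county mean elevation within one region (or one
#' elevation band of a region): `ln(PD_i) = m * z_i + b`. Densities must be
#' computed over inhabitable area only. The slope is only used for
#' weighting when it is statistically significant (p < 0.05); otherwise the
#' region's fit is flagged unweighted and its w1 surface is flat (the
#' treatment applied to regions with no credible elevation-density
#' relationship).
#'
#' @param density_per_km2 County population densities (persons/km^2, > 0).
#' @param mean_elevation_m County mean elevations (m).
#' @param region Region id, recorded on the fit.
#' @param band Optional `c(z_lo, z_hi)` elevation band the fit covers.
#' @return Object of class `region_topo_fit`: `region`, `m` (1/m), `b`
#'   (ln persons/km^2), `p_value`, `weighted`, `n_fit`, `band`.
#' @export
fit_topo_relation <- function(density_per_km2, mean_elevation_m,
                              region = 1L, band = NULL) {
  ok <- is.finite(density_per_km2) & is.finite(mean_elevation_m) &
    density_per_km2 > 0
  d <- density_per_km2[ok]; z <- mean_elevation_m[ok]
  if (length(d) < 3L) {
    stop("fit error: region ", region, " has fewer than 3 usable counties",
         call. = FALSE)
  }
  if (stats::var(z) == 0) {
    stop("fit error: region ", region,
         " has zero variance in county elevation", call. = FALSE)
  }
  fit <- stats::lm(log(d) ~ z)
  co <- suppressWarnings(summary(fit))$coefficients
  p <- co["z", "Pr(>|t|)"]
  structure(list(region = region, m = unname(stats::coef(fit)[2]),
                 b = unname(stats::coef(fit)[1]), p_value = unname(p),
                 weighted = is.finite(p) && p < 0.05,
                 n_fit = length(d), band = band),
            class = "region_topo_fit")
}

#' @export
print.region_topo_fit <- function(x, ...) {
  cat(sprintf(
    "<region_topo_fit> region %s: ln(PD) = %.3g * z + %.3g (p = %.3g, %s, n = %d)\n",
    format(x$region), x$m, x$b, x$p_value,
    if (x$weighted) "weighted" else "unweighted", x$n_fit))
  invisible(x)
}

#' Topographic suitability weight w1
#'
#' `w1 = exp(m * z)` per pixel from the region's fitted slope. Regions
#' whose fit is flagged `weighted = FALSE` get a flat w1 of 1 regardless of
#' elevation. With a list of fits and a region raster the surface is
#' assembled region by region.
#'
#' @param elevation `value_raster` of elevation (m).
#' @param fit A `region_topo_fit`, or a list of them (one per region).
#' @param region_labels Optional `label_raster` of regions; required when
#'   `fit` is a list.
#' @return A `value_raster` of strictly positive weights (NA off-universe).
#' @export
topo_weight <- function(elevation, fit, region_labels = NULL) {
  spec <- elevation$spec
  z <- elevation$data
  w1 <- matrix(1, spec$n_rows, spec$n_cols)
  apply_fit <- function(fit, sel) {
    if (isTRUE(fit$weighted)) {
      w1[sel] <<- exp(fit$m * z[sel])
    } else {
      w1[sel] <<- 1
    }
  }
  if (inherits(fit, "region_topo_fit")) {
    apply_fit(fit, !is.na(z))
  } else {
    check_aligned(elevation, region_labels)
    if (is.null(region_labels)) {
      stop("a list of fits requires region_labels", call. = FALSE)
    }
    for (f in fit) {
      sel <- !is.na(z) & region_labels$data == f$region
      if (!is.null(f$band)) {
        sel <- sel & z >= f$band[1] & z < f$band[2]
      }
      apply_fit(f, sel)
    }
  }
  w1[is.na(z)] <- NA
  value_raster(spec, w1, name = "w1_topographic")
}

#' Intra-urban socioeconomic weight: inverse-power distance decay
#'
#' `w2 = max(r, r_min)^(-lambda)` where `r` is the distance (km) from the
#' urban center to the pixel center and `r_min = cell_size / 2` guards the
#' singularity at the center pixel. `lambda = 0` gives a flat weight of 1.
#'
#' @param extent Integer vector of linear pixel indices (the urban extent).
#' @param center Center `c(row, col)`.
#' @param lambda Density-gradient exponent (see [lambda_from_beta()]).
#' @param spec The `grid_spec`.
#' @return Numeric vector of weights, one per extent pixel.
#' @export
urban_distance_weight <- function(extent, center, lambda, spec) {
  stopifnot(is.finite(lambda))
  if (length(extent) == 0L) return(numeric(0))
  if (lambda == 0) return(rep(1, length(extent)))
  r <- pixel_distance(extent, center, spec)
  r <- pmax(r, spec$cell_size_km / 2)
  r^(-lambda)
}

#' Travel-range schedule
#'
#' The maximum urban influence distance `D_t` grew with transport
#' technology; it is interpolated log-linearly in time between anchor
#' decades (exponential growth) and clamped at the anchors outside their
#' span. Defaults: 30 km in 1790 rising to 100 km in 2000.
#'
#' @param anchors Named numeric vector `{decade = D_km}` with at least one
#'   anchor; values must be positive and nondecreasing in time.
#' @return List of class `travel_schedule`.
#' @export
travel_schedule <- function(anchors = c("1790" = 30, "2000" = 100)) {
  t <- as.numeric(names(anchors))
  stopifnot(length(anchors) >= 1, !anyNA(t))
  o <- order(t)
  t <- t[o]; v <- as.numeric(anchors)[o]
  if (any(v <= 0)) stop("config error: travel-range anchors must be > 0",
                        call. = FALSE)
  if (is.unsorted(v)) stop("config error: travel range must be nondecreasing",
                           call. = FALSE)
  structure(list(decades = t, d_km = v), class = "travel_schedule")
}

#' Travel range for a decade
#'
#' @param t Decade (year).
#' @param schedule A [travel_schedule()].
#' @return `D_t` in km.
#' @export
travel_range <- function(t, schedule = travel_schedule()) {
  td <- schedule$decades; v <- schedule$d_km
  if (length(td) == 1L) return(v)
  if (t <= td[1]) return(v[1])
  if (t >= td[length(td)]) return(v[length(v)])
  exp(stats::approx(td, log(v), xout = t)$y)
}

#' Rural socioeconomic weight: gravity model of market potential
#'
#' For each rural pixel `k`, over the urban areas within travel range
#' (`r_k_phi <= D_t`):
#' `w2_k = sum(P_phi / r_k_phi^2) / sum(1 / r_k_phi^2)`,
#' a population-weighted mean of in-range urban populations. Pixels with no
#' urban area in range get the neutral weight 1 so that allocation there
#' degrades gracefully to the remaining weights instead of zeroing out
#' remote counties. Distances are clamped at half a cell size.
#'
#' @param rural_pixels Integer vector of linear pixel indices.
#' @param urban_centers Matrix with columns `row`, `col` (one row per urban
#'   area present in decade `t`).
#' @param urban_populations Numeric vector matching `urban_centers`.
#' @param d_max_km Travel range `D_t` (km); see [travel_range()].
#' @param spec The `grid_spec`.
#' @return Numeric vector of weights, one per rural pixel.
#' @export
market_potential <- function(rural_pixels, urban_centers,
                             urban_populations, d_max_km, spec) {
  n <- length(rural_pixels)
  if (n == 0L) return(numeric(0))
  num <- numeric(n); den <- numeric(n)
  n_urban <- if (is.null(urban_centers)) 0L else nrow(urban_centers)
  kernels <- vector("list", n_urban)
  if (n_urban > 0L) {
    stopifnot(length(urban_populations) == n_urban)
    rc <- idx_to_rc(rural_pixels, spec)
    r_min <- spec$cell_size_km / 2
    for (j in seq_len(n_urban)) {
      r <- spec$cell_size_km * sqrt((rc[, "row"] - urban_centers[j, 1])^2 +
                                    (rc[, "col"] - urban_centers[j, 2])^2)
      in_range <- which(r <= d_max_km)
      if (!length(in_range)) next
      u <- 1 / pmax(r[in_range], r_min)^2
      kernels[[j]] <- list(at = in_range, u = u)
      den[in_range] <- den[in_range] + u
    }
    # accumulate populations against normalized kernels: a pixel with one
    # in-range source then gets exactly that source's population
    for (j in seq_len(n_urban)) {
      k <- kernels[[j]]
      if (is.null(k)) next
      num[k$at] <- num[k$at] + urban_populations[j] * (k$u / den[k$at])
    }
  }
  out <- rep(1, n)
  hit <- den > 0
  out[hit] <- num[hit]
  out
}

#' Max-normalize a weight layer within divisions
#'
#' Rescales a weight surface so its maximum is 1 within each division (or
#' globally when no division raster is given). Allocation is invariant to
#' any positive rescaling within an allocation zone, so this is cosmetic —
#' it keeps stored weight grids on a common 0-1 range.
#'
#' @param w A `value_raster` of nonnegative weights.
#' @param division_labels Optional `label_raster` of divisions.
#' @return A `value_raster` with per-division maxima of 1.
#' @export
normalize_weights <- function(w, division_labels = NULL) {
  m <- w$data
  if (is.null(division_labels)) {
    mx <- max(m, na.rm = TRUE)
    if (mx > 0) m <- m / mx
  } else {
    check_aligned(w, division_labels)
    for (d in setdiff(unique(as.vector(division_labels$data)), 0L)) {
      sel <- division_labels$data == d & !is.na(m)
      mx <- suppressWarnings(max(m[sel]))
      if (is.finite(mx) && mx > 0) m[sel] <- m[sel] / mx
    }
  }
  value_raster(w$spec, m, name = w$name)
}

#' Assemble the decade's socioeconomic weight surface w2
#'
#' Urban pixels get the inverse-power distance weight with their division's
#' `lambda`; rural pixels get the gravity-model market potential with the
#' decade's travel range.
#'
#' @param decade Decade (year).
#' @param extent_raster `label_raster` of urban extents for the decade
#'   (labels = urban ids).
#' @param registry An `urban_registry` with centers and per-decade
#'   populations.
#' @param scaling data.frame from [fit_scaling_by_division()] (needs
#'   `division`, `lambda`).
#' @param universe `label_raster` defining on-universe pixels (e.g. county
#'   labels): rural = on-universe and not urban.
#' @param schedule A [travel_schedule()].
#' @return A `value_raster` of w2 weights (NA off-universe).
#' @export
build_w2 <- function(decade, extent_raster, registry, scaling, universe,
                     schedule = travel_schedule()) {
  check_aligned(extent_raster, universe)
  spec <- universe$spec
  w2 <- matrix(NA_real_, spec$n_rows, spec$n_cols)
  on_univ <- universe$data != 0L
  w2[on_univ] <- 1
  lam <- stats::setNames(scaling$lambda, scaling$division)

  pops <- registry$populations
  pops <- pops[pops$decade == decade & pops$population > 0, ]
  live_ids <- as.character(pops$urban_id)
  centers <- NULL; cpops <- numeric(0)
  for (uid in live_ids) {
    px <- which(extent_raster$data == as.integer(uid))
    cen <- registry$centers[[uid]]
    if (length(px) > 0L) {
      dv <- registry$areas$division[registry$areas$urban_id ==
                                      as.integer(uid)][1]
      w2[px] <- urban_distance_weight(px, cen, lam[[as.character(dv)]],
                                      spec)
    }
    centers <- rbind(centers, cen)
    cpops <- c(cpops, pops$population[pops$urban_id == as.integer(uid)])
  }
  rural <- which(on_univ & extent_raster$data == 0L)
  w2[rural] <- market_potential(rural, centers, cpops,
                                travel_range(decade, schedule), spec)
  value_raster(spec, w2, name = sprintf("w2_socioeconomic_%s", decade))
}
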