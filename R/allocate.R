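# Dasymetric allocation. Within each allocation zone Z (an urban-area /
# county intersection, a county-rural remainder, or a whole county for the
# simplest model) the zone's census population P_Z is spread as
#
#   P_k = w0_k * w1_k^s * w2_k^d / sum_Z(w0 * w1^s * w2^d) * P_Z
#
# Five nested models use progressively more of the weights:
#   M1  one zone per county, uniform
#   M2  urban / rural zones, uniform within each
#   M3  M2 restricted to inhabitable pixels (w0)
#   M4  M3 times topographic suitability (w1^s)
#   M5  M4 times socioeconomic desirability (w2^d)

MODEL_NAMES <- c("M1", "M2", "M3", "M4", "M5")

#' Allocate one zone's population across its pixels
#'
#' Normalized-product allocation with a uniform fallback: when every pixel
#' of the zone has zero weight (e.g. a fully non-inhabitable zone with
#' positive census population), the population is spread uniformly over the
#' whole zone rather than dropped — county totals are treated as
#' inviolable.
#'
#' @param p_zone Zone population `P_Z` (persons, >= 0).
#' @param w0 Numeric weight vector, one entry per zone pixel (its length
#'   defines the zone size). Binary for the inhabitability layer.
#' @param w1,w2 Nonnegative weight vectors (scalars are recycled).
#' @param s,d Exponents on `w1` and `w2`.
#' @return List: `population` (numeric vector summing to `p_zone`),
#'   `weight_sum`, `fallback` (logical).
#' @export
allocate_zone <- function(p_zone, w0, w1 = 1, w2 = 1, s = 1, d = 1) {
  n <- length(w0)
  if (n == 0L) {
    if (p_zone > 0) stop("allocation error: empty zone with positive population",
                         call. = FALSE)
    return(list(population = numeric(0), weight_sum = 0, fallback = FALSE))
  }
  stopifnot(p_zone >= 0, s >= 0, d >= 0)
  w <- rep(w0, length.out = n) * rep(w1, length.out = n)^s *
    rep(w2, length.out = n)^d
  tot <- sum(w)
  if (!is.finite(tot)) stop("allocation error: non-finite zone weights",
                            call. = FALSE)
  if (tot == 0) {
    list(population = rep(p_zone / n, n), weight_sum = 0, fallback = TRUE)
  } else {
    list(population = w / tot * p_zone, weight_sum = tot, fallback = FALSE)
  }
}

# Resolve a possibly per-division exponent for one division.
exponent_for <- function(x, division) {
  if (length(x) == 1L && is.null(names(x))) return(as.numeric(x))
  v <- x[[as.character(division)]]
  if (is.null(v) || is.na(v)) stop("no exponent for division ", division,
                                   call. = FALSE)
  as.numeric(v)
}

#' Run one allocation model for one decade
#'
#' @param model One of `"M1"` … `"M5"`.
#' @param decade Decade (year).
#' @param counties `label_raster` of counties.
#' @param census data.frame `unit_id`, `decade`, `population` of county
#'   totals.
#' @param extent_raster `label_raster` of urban extents for the decade
#'   (labels = urban ids); required from M2 up.
#' @param urban_pops data.frame `urban_id`, `county`, `population` for the
#'   decade (see [urban_populations()]); required from M2 up.
#' @param w0,w1,w2 `value_raster` weight layers (w0 from M3, w1 from M4,
#'   w2 for M5).
#' @param s,d Exponents: scalars or named vectors by division (then
#'   `divisions` is required). Ignored by models that do not use the layer.
#' @param divisions Optional `label_raster` of divisions for per-division
#'   exponents.
#' @return Object of class `allocation_result`: `model`, `decade`,
#'   `raster` (a `value_raster`, persons per pixel, fractional), and
#'   `diagnostics` (one row per zone: ids, population, weight sum,
#'   fallback flag).
#' @export
run_model <- function(model, decade, counties, census,
                      extent_raster = NULL, urban_pops = NULL,
                      w0 = NULL, w1 = NULL, w2 = NULL,
                      s = 1, d = 1, divisions = NULL) {
  model <- match.arg(model, MODEL_NAMES)
  check_aligned(counties, extent_raster, w0, w1, w2, divisions)
  spec <- counties$spec
  use_urban <- model != "M1"
  use_w0 <- model %in% c("M3", "M4", "M5")
  use_w1 <- model %in% c("M4", "M5")
  use_w2 <- model == "M5"
  if (use_urban && (is.null(extent_raster) || is.null(urban_pops))) {
    stop("configuration error: ", model,
         " needs urban extents and populations", call. = FALSE)
  }
  if (use_w0 && is.null(w0)) stop("configuration error: ", model,
                                  " needs w0", call. = FALSE)
  if (use_w1 && is.null(w1)) stop("configuration error: ", model,
                                  " needs w1", call. = FALSE)
  if (use_w2 && is.null(w2)) stop("configuration error: ", model,
                                  " needs w2", call. = FALSE)

  cen <- census[census$decade == decade, ]
  if (!nrow(cen)) stop("configuration error: no census rows for decade ",
                       decade, call. = FALSE)
  ptot <- stats::setNames(cen$population, cen$unit_id)

  cmat <- counties$data
  out <- matrix(NA_real_, spec$n_rows, spec$n_cols)
  out[cmat != 0L] <- 0
  diag_rows <- list()

  layer <- function(w, px, default = 1) {
    if (is.null(w)) rep(default, length(px)) else {
      v <- w$data[px]
      v[is.na(v)] <- default
      v
    }
  }

  county_ids <- sort(unique(as.vector(cmat[cmat != 0L])))
  for (ci in county_ids) {
    p_t <- unname(ptot[as.character(ci)])
    if (is.na(p_t)) stop("configuration error: county ", ci,
                           " missing from census table", call. = FALSE)
    county_px <- which(cmat == ci)
    dv <- if (is.null(divisions)) NA else divisions$data[county_px[1]]
    s_i <- if (use_w1) exponent_for(s, if (is.na(dv)) 1 else dv) else 0
    d_i <- if (use_w2) exponent_for(d, if (is.na(dv)) 1 else dv) else 0

    if (!use_urban) {
      al <- allocate_zone(p_t, w0 = rep(1, length(county_px)))
      out[county_px] <- al$population
      diag_rows[[length(diag_rows) + 1L]] <- data.frame(
        zone = "county", county = ci, urban_id = NA_integer_,
        population = p_t, n_pixels = length(county_px),
        weight_sum = al$weight_sum, fallback = al$fallback)
      next
    }

    emat <- extent_raster$data
    up <- urban_pops[urban_pops$county == ci, , drop = FALSE]
    urban_px_all <- integer(0)
    for (k in seq_len(nrow(up))) {
      uid <- up$urban_id[k]
      zone_px <- county_px[emat[county_px] == uid]
      if (length(zone_px) == 0L) {
        stop("configuration error: urban area ", uid,
             " has population but no extent pixels in county ", ci,
             " for decade ", decade, call. = FALSE)
      }
      urban_px_all <- c(urban_px_all, zone_px)
      al <- allocate_zone(
        up$population[k],
        w0 = if (use_w0) layer(w0, zone_px, 0) else
          rep(1, length(zone_px)),
        w1 = if (use_w1) layer(w1, zone_px) else 1,
        w2 = if (use_w2) layer(w2, zone_px) else 1,
        s = s_i, d = d_i)
      out[zone_px] <- al$population
      diag_rows[[length(diag_rows) + 1L]] <- data.frame(
        zone = "urban", county = ci, urban_id = uid,
        population = up$population[k], n_pixels = length(zone_px),
        weight_sum = al$weight_sum, fallback = al$fallback)
    }
    # extents present in the raster but missing a population record
    stray <- setdiff(unique(emat[county_px][emat[county_px] != 0L]),
                     up$urban_id)
    if (length(stray)) {
      stop("configuration error: extent(s) ", paste(stray, collapse = ", "),
           " in county ", ci, " lack urban population for decade ", decade,
           call. = FALSE)
    }
    rural_px <- setdiff(county_px, urban_px_all)
    p_r <- rural_population(p_t, up$population, county = ci,
                            decade = decade)
    if (length(rural_px) == 0L) {
      if (p_r > 0) stop("allocation error: county ", ci,
                        " has rural population but no rural pixels",
                        call. = FALSE)
    } else {
      al <- allocate_zone(
        p_r,
        w0 = if (use_w0) layer(w0, rural_px, 0) else
          rep(1, length(rural_px)),
        w1 = if (use_w1) layer(w1, rural_px) else 1,
        w2 = if (use_w2) layer(w2, rural_px) else 1,
        s = s_i, d = d_i)
      out[rural_px] <- al$population
      diag_rows[[length(diag_rows) + 1L]] <- data.frame(
        zone = "rural", county = ci, urban_id = NA_integer_,
        population = p_r, n_pixels = length(rural_px),
        weight_sum = al$weight_sum, fallback = al$fallback)
    }
  }
  structure(
    list(model = model, decade = decade,
         raster = value_raster(spec, out,
                               name = sprintf("population_%s_%s", model,
                                              decade)),
         diagnostics = do.call(rbind, diag_rows)),
    class = "allocation_result")
}

#' @export
print.allocation_result <- function(x, ...) {
  tot <- sum(x$raster$data, na.rm = TRUE)
  cat(sprintf("<allocation_result> %s, decade %s: %.6g persons in %d zones\n",
              x$model, format(x$decade), tot, nrow(x$diagnostics)))
  invisible(x)
}

#' Run a model across a decade list
#'
#' @inheritParams run_model
#' @param decades Integer vector of decades.
#' @param extent_rasters Named list of per-decade extent `label_raster`s.
#' @param registry An `urban_registry` supplying per-decade urban
#'   populations.
#' @param skip_decades Decades to omit (e.g. a decade with no digital urban
#'   data).
#' @return Named list of `allocation_result`, one per retained decade.
#' @export
run_history <- function(model, decades, counties, census,
                        extent_rasters = NULL, registry = NULL,
                        w0 = NULL, w1 = NULL, w2 = NULL,
                        s = 1, d = 1, divisions = NULL,
                        skip_decades = integer(0)) {
  decades <- setdiff(decades, skip_decades)
  out <- lapply(decades, function(t) {
    tryCatch({
      up <- if (!is.null(registry)) urban_populations(registry, t) else NULL
      w2_t <- if (is.list(w2) && !inherits(w2, "value_raster")) {
        w2[[as.character(t)]]
      } else w2
      run_model(model, t, counties, census,
                extent_raster = extent_rasters[[as.character(t)]],
                urban_pops = up, w0 = w0, w1 = w1, w2 = w2_t,
                s = s, d = d, divisions = divisions)
    }, error = function(e) {
      stop("decade ", t, ": ", conditionMessage(e), call. = FALSE)
    })
  })
  stats::setNames(out, decades)
}
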