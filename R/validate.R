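# Accuracy assessment and calibration. Products are scored against census
# units finer than the allocation input (tracts, county subdivisions) with
# the mean absolute relative error, and the weighting exponents are chosen
# by grid search on that score.

#' Mean absolute relative error over reference units
#'
#' `MARE = mean(|M_c - O_c| / O_c)` over the retained reference units.
#' Units smaller than `min_area_km2` are excluded before scoring (the grid
#' resolution cannot resolve them); units with zero observed population are
#' excluded with a warning rather than treated as infinite errors.
#'
#' @param modeled Named numeric vector (names = unit ids) of modeled unit
#'   populations, e.g. from [zonal_sum()].
#' @param observed Named numeric vector of census unit populations.
#' @param unit_areas_km2 Optional named numeric vector of unit areas; used
#'   with `min_area_km2` to drop sub-resolution units.
#' @param min_area_km2 Minimum unit area retained (default 1 km^2).
#' @return List of class `mare_score`: `mare`, `n_units`, `n_dropped_area`,
#'   `n_dropped_zero`.
#' @export
mare <- function(modeled, observed, unit_areas_km2 = NULL,
                 min_area_km2 = 1) {
  ids <- intersect(names(modeled), names(observed))
  if (length(ids) == 0L) stop("no matching unit ids between modeled and observed",
                              call. = FALSE)
  m <- modeled[ids]; o <- observed[ids]
  n_area <- 0L
  if (!is.null(unit_areas_km2)) {
    a <- unit_areas_km2[ids]
    keep <- !is.na(a) & a >= min_area_km2
    n_area <- sum(!keep)
    m <- m[keep]; o <- o[keep]
  }
  zero <- o <= 0
  if (any(zero)) {
    warning(sum(zero), " unit(s) with zero observed population excluded",
            call. = FALSE)
    m <- m[!zero]; o <- o[!zero]
  }
  if (length(o) == 0L) stop("no reference units retained for MARE",
                            call. = FALSE)
  structure(list(mare = mean(abs(m - o) / o), n_units = length(o),
                 n_dropped_area = n_area, n_dropped_zero = sum(zero)),
            class = "mare_score")
}

#' @export
print.mare_score <- function(x, ...) {
  cat(sprintf("<mare_score> MARE = %.4f over %d units\n", x$mare,
              x$n_units))
  invisible(x)
}

# Generic grid-search argmin with ties broken toward the smaller candidate.
argmin_grid <- function(candidates, evaluator) {
  candidates <- sort(candidates)
  scores <- vapply(candidates, function(v) as.numeric(evaluator(v)),
                   numeric(1))
  if (anyNA(scores)) stop("evaluator returned NA", call. = FALSE)
  best <- candidates[which.min(scores)]   # which.min takes the first tie
  list(value = best, scores = stats::setNames(scores, candidates))
}

#' Select the low-population tract cutoff for a division
#'
#' Evaluates each candidate cutoff with a user-supplied evaluator (which
#' should run the inhabitability-masked model and return the division's
#' MARE) and returns the candidate minimizing it; ties go to the smaller
#' cutoff.
#'
#' @param candidates Candidate cutoffs in persons (default
#'   `c(1000, 1500, 2000, 2500, 3000)`).
#' @param evaluator Function `cutoff -> MARE` (numeric or `mare_score`).
#' @return List: `cutoff`, `scores` (named numeric by candidate).
#' @export
select_cutoff_population <- function(candidates = c(1000, 1500, 2000,
                                                    2500, 3000),
                                     evaluator) {
  stopifnot(length(candidates) >= 1)
  r <- argmin_grid(candidates, function(v) {
    s <- evaluator(v)
    if (inherits(s, "mare_score")) s$mare else s
  })
  list(cutoff = r$value, scores = r$scores)
}

#' Calibrate a weighting exponent by grid search
#'
#' Returns the grid value minimizing the evaluator's MARE; ties go to the
#' smaller value. The topographic exponent `s` is calibrated first under
#' the model without socioeconomic weighting, then the socioeconomic
#' exponent `d` with `s` held fixed, matching the nested model
#' construction.
#'
#' @param which `"s"` or `"d"` (recorded on the result).
#' @param grid Nonempty numeric vector of candidate exponents.
#' @param evaluator Function `value -> MARE` (numeric or `mare_score`).
#' @return List: `which`, `value`, `scores`.
#' @export
calibrate_exponent <- function(which = c("s", "d"), grid, evaluator) {
  which <- match.arg(which)
  stopifnot(length(grid) >= 1)
  r <- argmin_grid(grid, function(v) {
    sc <- evaluator(v)
    if (inherits(sc, "mare_score")) sc$mare else sc
  })
  list(which = which, value = r$value, scores = r$scores)
}

#' Default calibration grids for the weighting exponents
#'
#' `s_grid` spans 0.2 to 3 in steps of 0.2. For `d` two presets exist: the
#' same coarse 0.2-3 span, and an extended preset whose low end continues
#' down to 0.02 for divisions whose optimum sits below 0.2.
#'
#' @param extended_d Use the extended low end for the `d` grid.
#' @return List with `s` and `d` numeric grids.
#' @export
exponent_grids <- function(extended_d = TRUE) {
  s <- seq(0.2, 3, by = 0.2)
  d <- if (extended_d) {
    c(0.02, 0.04, 0.06, 0.08, 0.10, seq(0.2, 2, by = 0.2))
  } else {
    seq(0.2, 3, by = 0.2)
  }
  list(s = s, d = d)
}

#' Sequentially calibrate (s, d) against reference unit populations
#'
#' Runs the topography-weighted model over the `s` grid (no socioeconomic
#' term), fixes the best `s`, then runs the full model over the `d` grid.
#' The objective is tract-level MARE for the calibration decade.
#'
#' @param decade Calibration decade.
#' @param counties,census,extent_raster,urban_pops,w0,w1,w2,divisions As in
#'   [run_model()].
#' @param reference Named numeric vector of observed reference-unit
#'   populations (e.g. tracts).
#' @param reference_labels `label_raster` of the reference units.
#' @param s_grid,d_grid Candidate grids (see [exponent_grids()]).
#' @param min_area_km2 Minimum reference-unit area retained.
#' @return List: `s`, `d`, `s_scores`, `d_scores`, `mare` (final model
#'   MARE at the calibrated pair).
#' @export
calibrate_model_exponents <- function(decade, counties, census,
                                      extent_raster, urban_pops,
                                      w0, w1, w2, reference,
                                      reference_labels,
                                      s_grid = exponent_grids()$s,
                                      d_grid = exponent_grids()$d,
                                      divisions = NULL,
                                      min_area_km2 = 1) {
  areas <- zone_areas(reference_labels)
  unit_areas <- stats::setNames(areas$area_km2, areas$zone)
  score <- function(model, s, d) {
    res <- run_model(model, decade, counties, census,
                     extent_raster = extent_raster,
                     urban_pops = urban_pops, w0 = w0, w1 = w1, w2 = w2,
                     s = s, d = d, divisions = divisions)
    agg <- zonal_sum(res$raster, reference_labels)
    mare(agg, reference, unit_areas, min_area_km2)$mare
  }
  cal_s <- calibrate_exponent("s", s_grid, function(v) score("M4", v, 0))
  cal_d <- calibrate_exponent("d", d_grid,
                              function(v) score("M5", cal_s$value, v))
  list(s = cal_s$value, d = cal_d$value,
       s_scores = cal_s$scores, d_scores = cal_d$scores,
       mare = min(cal_d$scores))
}

#' Model-effectiveness deltas from a MARE sequence
#'
#' The effectiveness of each added influence factor is the MARE reduction
#' relative to the next-simpler model: `MARE(M_i) - MARE(M_{i+1})` for
#' consecutive models.
#'
#' @param mare_by_model Named numeric vector with names among
#'   `"M1"`…`"M5"` (consecutive models required).
#' @return Named numeric vector of deltas, e.g. `"M1-M2"`.
#' @export
model_effectiveness <- function(mare_by_model) {
  present <- MODEL_NAMES[MODEL_NAMES %in% names(mare_by_model)]
  if (length(present) < 2L) stop("need at least two consecutive models",
                                 call. = FALSE)
  idx <- match(present, MODEL_NAMES)
  if (any(diff(idx) != 1L)) {
    stop("model gap: MARE values must cover consecutive models (have ",
         paste(present, collapse = ", "), ")", call. = FALSE)
  }
  v <- mare_by_model[present]
  d <- v[-length(v)] - v[-1]
  stats::setNames(as.numeric(d),
                  paste(present[-length(present)], present[-1], sep = "-"))
}

#' Score every model for one decade against reference units
#'
#' @inheritParams calibrate_model_exponents
#' @param models Character vector of models to score.
#' @param s,d Exponents used for M4/M5.
#' @return Object of class `validation_report`: data.frame `model`,
#'   `mare`, `n_units`, plus the effectiveness deltas.
#' @export
validate_models <- function(models = MODEL_NAMES, decade, counties, census,
                            extent_raster = NULL, urban_pops = NULL,
                            w0 = NULL, w1 = NULL, w2 = NULL,
                            s = 1, d = 1, divisions = NULL,
                            reference, reference_labels,
                            min_area_km2 = 1) {
  areas <- zone_areas(reference_labels)
  unit_areas <- stats::setNames(areas$area_km2, areas$zone)
  rows <- lapply(models, function(mo) {
    res <- run_model(mo, decade, counties, census,
                     extent_raster = extent_raster,
                     urban_pops = urban_pops, w0 = w0, w1 = w1, w2 = w2,
                     s = s, d = d, divisions = divisions)
    agg <- zonal_sum(res$raster, reference_labels)
    sc <- mare(agg, reference, unit_areas, min_area_km2)
    data.frame(model = mo, mare = sc$mare, n_units = sc$n_units)
  })
  tab <- do.call(rbind, rows)
  idx <- match(tab$model, MODEL_NAMES)
  deltas <- if (nrow(tab) >= 2 && all(diff(idx) == 1L)) {
    model_effectiveness(stats::setNames(tab$mare, tab$model))
  } else NULL
  structure(list(decade = decade, table = tab, effectiveness = deltas),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> decade %s\n", format(x$decade)))
  print(x$table, row.names = FALSE)
  if (!is.null(x$effectiveness)) {
    cat("MARE reduction: ",
        paste(sprintf("%s %.3f", names(x$effectiveness), x$effectiveness),
              collapse = ", "), "\n")
  }
  invisible(x)
}
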