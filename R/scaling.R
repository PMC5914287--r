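# Urban area-population power-law scaling A_U = alpha * P_U^beta, fitted
# per census division on the baseline decade, and the rural bookkeeping that
# splits county totals into urban and remainder-rural parts.

#' Fit the urban area-population power law for one division
#'
#' Ordinary least squares of `log10(area)` on `log10(population)`:
#' `A = alpha * P^beta` with `alpha = 10^intercept`, `beta = slope`. The
#' regression direction follows the prediction direction (area is predicted
#' from population when reconstructing historical extents). The intra-urban
#' density-gradient exponent `lambda = 2 - 2 * beta` is derived alongside.
#'
#' @param areas_km2 Urban footprint areas (km^2), one per urban area.
#' @param populations Matching urban populations (persons).
#' @param division Division id the fit belongs to.
#' @return An object of class `scaling_fit` with fields `division`, `alpha`,
#'   `beta`, `lambda`, `n_fit`, `r_squared`.
#' @export
fit_area_population_scaling <- function(areas_km2, populations,
                                        division = 1L) {
  if (length(areas_km2) != length(populations)) {
    stop("areas and populations differ in length")
  }
  ok <- is.finite(areas_km2) & is.finite(populations) &
    areas_km2 > 0 & populations > 0
  a <- areas_km2[ok]; p <- populations[ok]
  if (length(a) < 3L) {
    stop("fit error: division ", division,
         " has fewer than 3 usable urban areas", call. = FALSE)
  }
  if (stats::var(log10(p)) == 0) {
    stop("fit error: division ", division,
         " has zero variance in log population", call. = FALSE)
  }
  fit <- stats::lm(log10(a) ~ log10(p))
  beta <- unname(stats::coef(fit)[2])
  alpha <- 10^unname(stats::coef(fit)[1])
  structure(
    list(division = division, alpha = alpha, beta = beta,
         lambda = lambda_from_beta(beta), n_fit = length(a),
         r_squared = suppressWarnings(summary(fit)$r.squared)),
    class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "<scaling_fit> division %s: A = %.4g * P^%.4f (lambda = %.4f, n = %d, R2 = %.3f)\n",
    format(x$division), x$alpha, x$beta, x$lambda, x$n_fit, x$r_squared))
  invisible(x)
}

#' Predict an urban footprint area from population
#'
#' @param population Urban population (persons), positive.
#' @param fit A `scaling_fit` (or any list with `alpha` and `beta`).
#' @return Predicted area `alpha * P^beta` in km^2.
#' @export
predict_area <- function(population, fit) {
  if (any(!is.finite(population) | population <= 0)) {
    stop("domain error: population must be positive", call. = FALSE)
  }
  fit$alpha * population^fit$beta
}

#' Density-gradient exponent from the scaling factor
#'
#' The intra-urban density gradient `lambda` (exponent of the inverse-power
#' decay of density with distance from the urban center) is linked to the
#' area-population scaling factor by `lambda = 2 - 2 * beta`.
#'
#' @param beta Scaling factor (dimensionless).
#' @return `2 - 2 * beta`.
#' @export
lambda_from_beta <- function(beta) {
  stopifnot(is.finite(beta))
  2 - 2 * beta
}

#' Rural population of a county by difference
#'
#' `P_R = P_T - sum(P_U)` over the county's urban areas. A negative result
#' means the census tables disagree and is raised as an inconsistency error.
#'
#' @param total Total county population `P_T`.
#' @param urban_pops Numeric vector of urban-area populations in the county
#'   (may be empty).
#' @param county,decade Identifiers used in the error message.
#' @return Rural population (>= 0).
#' @export
rural_population <- function(total, urban_pops = numeric(0),
                             county = NA, decade = NA) {
  stopifnot(total >= 0, all(urban_pops >= 0))
  r <- total - sum(urban_pops)
  if (r < 0) {
    stop(sprintf(
      "inconsistency error: county %s decade %s: urban population %.6g exceeds total %.6g",
      format(county), format(decade), sum(urban_pops), total),
      call. = FALSE)
  }
  r
}

#' Rural area of a county by difference
#'
#' `A_R = A_T - sum(A_U)`, mirroring [rural_population()].
#'
#' @param total_area_km2 County total area.
#' @param urban_areas_km2 Vector of urban footprint areas in the county.
#' @param county Identifier used in the error message.
#' @return Rural area in km^2 (>= 0).
#' @export
rural_area <- function(total_area_km2, urban_areas_km2 = numeric(0),
                       county = NA) {
  stopifnot(total_area_km2 >= 0, all(urban_areas_km2 >= 0))
  r <- total_area_km2 - sum(urban_areas_km2)
  if (r < 0) {
    stop(sprintf(
      "inconsistency error: county %s: urban area %.6g km2 exceeds total %.6g km2",
      format(county), sum(urban_areas_km2), total_area_km2),
      call. = FALSE)
  }
  r
}

#' Fit the scaling law for every division in an urban table
#'
#' @param urban data.frame with columns `urban_id`, `division`, `area_km2`,
#'   `population` (one row per urban area, baseline decade).
#' @return data.frame with one row per division: `division`, `alpha`,
#'   `beta`, `lambda`, `n`, `r2`.
#' @export
fit_scaling_by_division <- function(urban) {
  need <- c("division", "area_km2", "population")
  stopifnot(all(need %in% names(urban)))
  out <- lapply(split(urban, urban$division), function(d) {
    f <- fit_area_population_scaling(d$area_km2, d$population,
                                     division = d$division[1])
    data.frame(division = f$division, alpha = f$alpha, beta = f$beta,
               lambda = f$lambda, n = f$n_fit, r2 = f$r_squared)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
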