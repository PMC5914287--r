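# Historical urban-extent reconstruction. Two simplifying assumptions make
# backprojection possible: urbanization is monotonic (areas settled by the
# baseline decade stay urban), and urban areas grow outward from a center.
# An earlier extent is therefore the distance-ranked innermost subset of
# the baseline footprint whose pixel count matches the area predicted from
# the scaling law for that decade's population.

#' Center pixel of an urban footprint
#'
#' Unweighted centroid of the footprint pixel centers, snapped to the
#' nearest footprint pixel. Distance ties are broken by smallest row, then
#' smallest column, so the center is reproducible across platforms.
#'
#' @param footprint Integer vector of linear pixel indices.
#' @param spec The `grid_spec` the indices refer to.
#' @return Named integer vector `c(row, col)`.
#' @export
urban_center <- function(footprint, spec) {
  if (length(footprint) == 0L) {
    stop("domain error: empty urban footprint", call. = FALSE)
  }
  rc <- idx_to_rc(footprint, spec)
  cen <- c(mean(rc[, "row"]), mean(rc[, "col"]))
  d2 <- (rc[, "row"] - cen[1])^2 + (rc[, "col"] - cen[2])^2
  ord <- order(d2, rc[, "row"], rc[, "col"])
  c(row = unname(rc[ord[1], "row"]), col = unname(rc[ord[1], "col"]))
}

# Total order on footprint pixels used for concentric shrinking: distance
# from center, then angle from east (counterclockwise, north-up), then row,
# then column. The angle term makes growth fill rings consistently instead
# of depending on storage order.
order_footprint <- function(footprint, center, spec) {
  rc <- idx_to_rc(footprint, spec)
  dr <- rc[, "row"] - center[1]   # positive = south of center
  dc <- rc[, "col"] - center[2]
  d2 <- dr^2 + dc^2
  ang <- atan2(-dr, dc) %% (2 * pi)
  footprint[order(d2, ang, rc[, "row"], rc[, "col"])]
}

#' Reconstruct an urban area's per-decade extents by concentric shrinking
#'
#' The baseline footprint is sorted by distance to its center; the extent
#' for decade `t` is the first `n_t` pixels of that ordering, where
#' `n_t = clamp(round(A_t / cell_area), 1, |footprint|)` and `A_t` is the
#' target (scaling-law) area for that decade. Nesting across decades holds
#' by construction. A target exceeding the baseline footprint is clamped to
#' the full footprint with a warning (backprojection should shrink, not
#' grow); the minimum extent is one pixel while the area exists.
#'
#' @param footprint Integer vector of linear pixel indices (baseline
#'   extent).
#' @param target_areas_km2 Named numeric vector of target areas by decade;
#'   `NA` marks decades in which the urban area does not exist.
#' @param spec The `grid_spec`.
#' @param center Optional center `c(row, col)`; defaults to
#'   [urban_center()].
#' @return An object of class `urban_extent_series`: list with `center`,
#'   `ordered_pixels`, `n_by_decade` (named integer, `NA` where absent) and
#'   `extent(decade)` accessor via [extent_pixels()].
#' @export
delineate_history <- function(footprint, target_areas_km2, spec,
                              center = NULL) {
  if (length(footprint) == 0L) {
    stop("domain error: empty urban footprint", call. = FALSE)
  }
  if (is.null(center)) center <- urban_center(footprint, spec)
  ordered <- order_footprint(footprint, center, spec)
  n_max <- length(ordered)
  ca <- cell_area_km2(spec)
  n_by_decade <- vapply(target_areas_km2, function(a) {
    if (is.na(a)) return(NA_integer_)
    if (a <= 0) stop("target area must be positive where the area exists")
    n <- as.integer(round_half_up(a / ca))
    if (n > n_max) {
      warning("target area ", a, " km2 exceeds baseline footprint (",
              n_max * ca, " km2); clamped", call. = FALSE)
      n <- n_max
    }
    max(n, 1L)
  }, integer(1))
  structure(list(center = center, ordered_pixels = ordered,
                 n_by_decade = n_by_decade),
            class = "urban_extent_series")
}

#' Extent pixels of a reconstructed series in one decade
#'
#' @param series An `urban_extent_series`.
#' @param decade Decade (must be a name of `n_by_decade`).
#' @return Integer vector of linear pixel indices; `integer(0)` if the
#'   urban area does not exist that decade.
#' @export
extent_pixels <- function(series, decade) {
  key <- as.character(decade)
  if (!key %in% names(series$n_by_decade)) return(integer(0))
  n <- series$n_by_decade[[key]]
  if (is.null(n) || is.na(n)) return(integer(0))
  series$ordered_pixels[seq_len(n)]
}

#' Fraction of reference urban pixels overlapped by a model mask
#'
#' `|model intersect reference| / |reference|`: the share of reference
#' urban pixels that the reconstruction also marks urban.
#'
#' @param model_mask,reference_mask Logical matrices (or 0/1 matrices) of
#'   identical shape, or integer vectors of linear pixel indices.
#' @return Fraction in `[0, 1]`; `NA` with a warning when the reference is
#'   empty.
#' @export
overlap_fraction <- function(model_mask, reference_mask) {
  if (is.matrix(model_mask) || is.matrix(reference_mask)) {
    stopifnot(is.matrix(model_mask), is.matrix(reference_mask),
              all(dim(model_mask) == dim(reference_mask)))
    model_mask <- which(model_mask != 0)
    reference_mask <- which(reference_mask != 0)
  }
  n_ref <- length(reference_mask)
  if (n_ref == 0L) {
    warning("empty reference mask: overlap undefined", call. = FALSE)
    return(NA_real_)
  }
  length(intersect(model_mask, reference_mask)) / n_ref
}

#' Reconstruct extents for every urban area in a registry
#'
#' Applies [delineate_history()] per urban area, with target areas from the
#' division scaling fits and the registry's per-decade populations, and
#' rasterizes the result into one urban label raster per decade.
#'
#' @param registry An `urban_registry` (see [urban_registry()]).
#' @param scaling data.frame from [fit_scaling_by_division()].
#' @param decades Integer vector of decades to reconstruct.
#' @param spec The `grid_spec`.
#' @param baseline_decade Decade whose footprints are observed; that decade
#'   keeps the observed footprint rather than a scaling-law prediction.
#'   Defaults to `max(decades)`.
#' @return List with `series` (per urban id) and `extent_rasters` (named
#'   list of `label_raster`, one per decade; labels = urban ids).
#' @export
delineate_registry <- function(registry, scaling, decades, spec,
                               baseline_decade = max(decades)) {
  stopifnot(inherits(registry, "urban_registry"))
  fits <- split(scaling, scaling$division)
  series <- list()
  for (uid in names(registry$footprints)) {
    info <- registry$areas[registry$areas$urban_id == as.integer(uid), ][1, ]
    fit <- fits[[as.character(info$division)]]
    if (is.null(fit)) {
      stop("no scaling fit for division ", info$division, call. = FALSE)
    }
    pops <- registry$populations
    pops <- pops[pops$urban_id == as.integer(uid), ]
    tgt <- stats::setNames(rep(NA_real_, length(decades)), decades)
    fp <- registry$footprints[[uid]]
    for (t in decades) {
      p <- pops$population[pops$decade == t]
      if (length(p) == 1L && p > 0) {
        tgt[[as.character(t)]] <- if (t == baseline_decade) {
          length(fp) * cell_area_km2(spec)
        } else {
          predict_area(p, fit)
        }
      }
    }
    series[[uid]] <- delineate_history(registry$footprints[[uid]], tgt,
                                       spec, center = registry$centers[[uid]])
  }
  rasters <- lapply(decades, function(t) {
    m <- matrix(0L, spec$n_rows, spec$n_cols)
    for (uid in names(series)) {
      px <- extent_pixels(series[[uid]], t)
      m[px] <- as.integer(uid)
    }
    label_raster(spec, m, level = "urban")
  })
  names(rasters) <- decades
  list(series = series, extent_rasters = rasters)
}
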