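# Registry of urban areas: static attributes, per-decade populations, and
# baseline footprints. The census definition of an urban area (population
# >= 2500) is enforced here.

#' Construct an urban registry
#'
#' @param areas data.frame with one row per urban area: `urban_id`,
#'   `division`, `county`, and baseline `area_km2`, `population`.
#' @param populations data.frame `urban_id`, `decade`, `population`
#'   (persons); rows only for decades the urban area exists (population
#'   at least `min_population`).
#' @param footprints Named list (by urban id) of integer linear pixel
#'   index vectors — the baseline footprints.
#' @param centers Named list (by urban id) of `c(row, col)` centers.
#' @param min_population Census population threshold defining an urban
#'   area (default 2500).
#' @return Object of class `urban_registry`.
#' @export
urban_registry <- function(areas, populations, footprints, centers,
                           min_population = 2500) {
  stopifnot(all(c("urban_id", "division", "county") %in% names(areas)),
            all(c("urban_id", "decade", "population") %in%
                  names(populations)))
  if (nrow(populations) && any(populations$population < min_population)) {
    stop("urban registry lists areas below the ", min_population,
         "-person urban threshold", call. = FALSE)
  }
  ids <- as.character(areas$urban_id)
  stopifnot(all(ids %in% names(footprints)),
            all(ids %in% names(centers)))
  structure(list(areas = areas, populations = populations,
                 footprints = footprints, centers = centers,
                 min_population = min_population),
            class = "urban_registry")
}

#' @export
print.urban_registry <- function(x, ...) {
  cat(sprintf("<urban_registry> %d urban areas, %d area-decade records\n",
              nrow(x$areas), nrow(x$populations)))
  invisible(x)
}

#' Per-decade urban populations as a lookup table
#'
#' @param registry An `urban_registry`.
#' @param decade Decade (year).
#' @return data.frame `urban_id`, `county`, `division`, `population` for
#'   the urban areas existing that decade.
#' @export
urban_populations <- function(registry, decade) {
  p <- registry$populations
  p <- p[p$decade == decade & p$population > 0, c("urban_id", "population")]
  merge(p, registry$areas[, c("urban_id", "county", "division")],
        by = "urban_id", sort = TRUE)
}
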