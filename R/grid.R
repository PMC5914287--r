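# Raster / table data model shared by every stage of the pipeline.
#
# Rasters are plain numeric matrices wrapped with a grid_spec; row 1 is the
# northernmost row, columns run west to east, and pixel centers sit at
# origin + (col - 0.5, row - 0.5) * cell_size in projected km. All distances
# are Euclidean between pixel centers on this planar grid.

#' Grid specification for an aligned raster stack
#'
#' Every raster in a session shares one `grid_spec`: the same shape, cell
#' size, origin and nodata sentinel. Areas are always pixel counts times
#' `cell_size_km^2`; there is no sub-pixel geometry.
#'
#' @param n_rows,n_cols Grid dimensions (rows are north-south).
#' @param cell_size_km Cell edge length in projected km (default 1).
#' @param origin Numeric length-2, lower-left corner (x, y) in km.
#' @param nodata_value Sentinel written to nodata cells on disk.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size_km = 1,
                      origin = c(0, 0), nodata_value = -9999) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size_km > 0,
            length(origin) == 2, is.finite(nodata_value))
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size_km = as.numeric(cell_size_km),
         origin = as.numeric(origin),
         nodata_value = as.numeric(nodata_value)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %.3g km cell, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size_km, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Pixel area implied by a grid spec
#' @param spec A `grid_spec`.
#' @return Area of one pixel in km^2.
#' @export
cell_area_km2 <- function(spec) spec$cell_size_km^2

same_spec <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$cell_size_km, b$cell_size_km))
}

check_aligned <- function(..., what = "rasters") {
  rs <- Filter(Negate(is.null), list(...))
  if (length(rs) < 2) return(invisible(TRUE))
  s0 <- rs[[1]]$spec
  for (r in rs[-1]) {
    if (!same_spec(s0, r$spec)) {
      stop("alignment error: ", what, " do not share one grid_spec",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Construct a label raster
#'
#' Labels are 1-based positive integers identifying spatial units (county,
#' tract, subdivision, division, region, or urban area); 0 marks pixels
#' outside the study universe.
#'
#' @param spec A `grid_spec`.
#' @param labels Integer matrix `n_rows x n_cols` (row 1 = north).
#' @param level Unit level the labels encode, e.g. `"county"`.
#' @return An object of class `label_raster`.
#' @export
label_raster <- function(spec, labels, level = "unit") {
  labels <- matrix(as.integer(round(labels)), spec$n_rows, spec$n_cols)
  if (any(labels < 0L, na.rm = TRUE)) stop("labels must be >= 0")
  labels[is.na(labels)] <- 0L
  structure(list(spec = spec, data = labels, level = level),
            class = c("label_raster", "raster_layer"))
}

#' Construct a value raster
#'
#' @param spec A `grid_spec`.
#' @param values Numeric matrix `n_rows x n_cols`; `NA` marks off-universe
#'   pixels.
#' @param name Optional layer name (e.g. `"elevation_m"`).
#' @return An object of class `value_raster`.
#' @export
value_raster <- function(spec, values, name = "value") {
  values <- matrix(as.numeric(values), spec$n_rows, spec$n_cols)
  structure(list(spec = spec, data = values, name = name),
            class = c("value_raster", "raster_layer"))
}

#' @export
print.raster_layer <- function(x, ...) {
  kind <- if (inherits(x, "label_raster")) {
    sprintf("label_raster[%s], %d units", x$level,
            length(setdiff(unique(as.vector(x$data)), 0L)))
  } else {
    rng <- range(x$data, na.rm = TRUE)
    sprintf("value_raster[%s], range [%.4g, %.4g]", x$name, rng[1], rng[2])
  }
  cat(sprintf("<%s> %d x %d\n", kind, x$spec$n_rows, x$spec$n_cols))
  invisible(x)
}

# Linear pixel index <-> (row, col). R matrices are column-major; all pixel
# sets in the package are integer vectors of such linear indices.
idx_to_rc <- function(idx, spec) {
  cbind(row = ((idx - 1L) %% spec$n_rows) + 1L,
        col = ((idx - 1L) %/% spec$n_rows) + 1L)
}

rc_to_idx <- function(row, col, spec) {
  (as.integer(col) - 1L) * spec$n_rows + as.integer(row)
}

# Euclidean distance (km) from a reference pixel to a set of pixels.
pixel_distance <- function(idx, ref_rc, spec) {
  rc <- idx_to_rc(idx, spec)
  ref_rc <- unname(ref_rc)
  unname(spec$cell_size_km *
           sqrt((rc[, "row"] - ref_rc[1])^2 + (rc[, "col"] - ref_rc[2])^2))
}

#' Read an Esri ASCII grid
#'
#' Reads the plain-text `.asc` dialect (header lines `ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `nodata_value`, then rows north to
#' south). Nodata cells map to 0 for label rasters and `NA` for value
#' rasters.
#'
#' @param path File path.
#' @param kind `"label"` or `"value"`.
#' @param spec Optional session `grid_spec`; if supplied the file must match
#'   its shape and cell size or an alignment error is raised.
#' @param level,name Passed through to the raster constructor.
#' @return A `label_raster` or `value_raster`.
#' @export
read_raster <- function(path, kind = c("value", "label"), spec = NULL,
                        level = "unit", name = "value") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("I/O error: cannot read '", path, "'",
                               call. = FALSE)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                   "cellsize", "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  for (k in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[k]])) {
      stop("I/O error: '", path, "' lacks ASCII-grid header field ", k,
           call. = FALSE)
    }
  }
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop("I/O error: '", path, "' has ", length(vals), " cells, expected ",
         nr * nc, call. = FALSE)
  }
  # file rows run north to south, matching our row order
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  file_spec <- grid_spec(
    nr, nc, cell_size_km = hdr$cellsize,
    origin = c(if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner,
               if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner),
    nodata_value = nodata)
  if (!is.null(spec)) {
    if (!same_spec(spec, file_spec)) {
      stop("alignment error: '", path, "' does not match the session grid",
           call. = FALSE)
    }
    file_spec <- spec
  }
  is_nd <- m == nodata
  if (kind == "label") {
    m[is_nd] <- 0
    label_raster(file_spec, m, level = level)
  } else {
    m[is_nd] <- NA_real_
    value_raster(file_spec, m, name = name)
  }
}

#' Write a raster as an Esri ASCII grid
#'
#' Off-universe pixels (label 0, or `NA` values) are written as the spec's
#' nodata sentinel. `read_raster(write_raster(x))` reproduces cell values
#' exactly.
#'
#' @param x A `label_raster` or `value_raster`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path) {
  spec <- x$spec
  m <- x$data
  if (inherits(x, "label_raster")) {
    m <- matrix(as.numeric(m), nrow(m), ncol(m))
    m[m == 0] <- spec$nodata_value
  } else {
    m[is.na(m)] <- spec$nodata_value
  }
  hdr <- c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$origin[1]),
    sprintf("yllcorner %.10g", spec$origin[2]),
    sprintf("cellsize %.10g", spec$cell_size_km),
    sprintf("nodata_value %.10g", spec$nodata_value))
  body <- apply(m, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Zonal sum of a value raster over labelled zones
#'
#' Sums `values` over the on-universe pixels of every nonzero zone label.
#' Used throughout for census bookkeeping: summing an allocation raster over
#' county labels must return each county's census total.
#'
#' @param values A `value_raster`.
#' @param zones A `label_raster` aligned with `values`.
#' @return Named numeric vector, names = zone ids present in `zones`.
#' @export
zonal_sum <- function(values, zones) {
  check_aligned(values, zones)
  v <- as.vector(values$data)
  z <- as.vector(zones$data)
  keep <- z != 0L & !is.na(v)
  out <- tapply(v[keep], z[keep], sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Zonal mean of a value raster over labelled zones
#'
#' @inheritParams zonal_sum
#' @return Named numeric vector of per-zone arithmetic means over
#'   on-universe pixels. Zones whose pixels are all off-universe are
#'   reported as `NA` (missing, not zero).
#' @export
zonal_mean <- function(values, zones) {
  check_aligned(values, zones)
  v <- as.vector(values$data)
  z <- as.vector(zones$data)
  ids <- sort(unique(z[z != 0L]))
  keep <- z != 0L & !is.na(v)
  m <- tapply(v[keep], z[keep], mean)
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  out[names(m)] <- as.numeric(m)
  out
}

#' Per-zone pixel counts and areas
#'
#' @param zones A `label_raster`.
#' @return data.frame with columns `zone`, `n_pixels`, `area_km2`.
#' @export
zone_areas <- function(zones) {
  z <- as.vector(zones$data)
  tab <- table(z[z != 0L])
  data.frame(zone = as.integer(names(tab)),
             n_pixels = as.integer(tab),
             area_km2 = as.integer(tab) * cell_area_km2(zones$spec),
             row.names = NULL)
}

#' Read a census table from CSV
#'
#' Expected columns: `unit_id`, `decade`, `population` and optionally
#' `area_km2` (county tables only).
#'
#' @param path CSV file path.
#' @return data.frame with those columns.
#' @export
read_census_table <- function(path) {
  if (!file.exists(path)) stop("I/O error: cannot read '", path, "'",
                               call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("unit_id", "decade", "population")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("census table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(df$population < 0)) stop("census table has negative populations")
  df
}

#' @rdname read_census_table
#' @param df Census data.frame to write.
#' @export
write_census_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Label 4-connected components of a logical matrix. Small pure-R BFS;
# grids in this package are at most a few hundred cells on a side.
connected_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  queue <- integer(nr * nc)
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue[1L] <- start
    lab[start] <- cur
    head <- 1L; tail <- 1L
    while (head <= tail) {
      p <- queue[head]; head <- head + 1L
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (q in c(if (r > 1L) p - 1L, if (r < nr) p + 1L,
                  if (cc > 1L) p - nr, if (cc < nc) p + nr)) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          tail <- tail + 1L
          queue[tail] <- q
        }
      }
    }
  }
  lab
}

# round() halves away from zero: extent pixel counts must not depend on the
# IEEE round-to-even of the platform's round().
round_half_up <- function(x) floor(x + 0.5)
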