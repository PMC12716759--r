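#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum(|pX_i - pY_i|)` over the grid cells valid in both
#' surfaces. With `normalize = TRUE` (the default) each surface is first
#' rescaled to unit sum over the shared cells, which guarantees `D` in
#' `[0, 1]` (1 = identical niches, 0 = completely separated). With
#' `normalize = FALSE` the raw habitat-suitability values are compared
#' directly and `D` may leave `[0, 1]`; the report flags which mode was used.
#'
#' @param surface_x,surface_y co-registered `raster_grid` suitability
#'   surfaces.
#' @param normalize rescale both surfaces to unit sum first (default `TRUE`).
#' @return object of class `overlap_report`: list with `D`, `category`
#'   (overlap band, `NA` when D falls outside `[0, 1]`), `n_cells`,
#'   `normalized`.
#' @export
schoeners_d <- function(surface_x, surface_y, normalize = TRUE) {
  if (!same_geometry(surface_x, surface_y))
    stop("schoeners_d: surfaces are not co-registered")
  ok <- !surface_x$nodata_mask & !surface_y$nodata_mask
  if (!any(ok)) stop("schoeners_d: no shared valid cells")
  px <- surface_x$values[ok]; py <- surface_y$values[ok]
  if (normalize) {
    if (sum(px) <= 0 || sum(py) <= 0)
      stop("schoeners_d: zero-sum surface cannot be normalized")
    px <- px / sum(px); py <- py / sum(py)
  }
  D <- 1 - 0.5 * sum(abs(px - py))
  category <- if (D >= 0 && D <= 1) classify_overlap(D) else NA_character_
  structure(list(D = D, category = category, n_cells = sum(ok),
                 normalized = normalize),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> D = %.4f (%s), %d cells%s\n", x$D,
              ifelse(is.na(x$category), "out of [0,1]", x$category),
              x$n_cells, if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Overlap category bands for Schoener's D
#'
#' Half-open bands: very low `[0, 0.2)`, low `[0.2, 0.4)`, moderate
#' `[0.4, 0.6)`, high `[0.6, 0.8)`, very high `[0.8, 1]` — each boundary
#' belongs to the upper band and the top band is closed at 1.
#'
#' @param D overlap value in `[0, 1]`.
#' @return character scalar.
#' @export
classify_overlap <- function(D) {
  if (is.na(D) || D < 0 || D > 1)
    stop("classify_overlap: D must lie in [0, 1]")
  D <- round(D, 12)  # keep exact band boundaries immune to float noise
  if (D >= 0.8) "very high"
  else if (D >= 0.6) "high"
  else if (D >= 0.4) "moderate"
  else if (D >= 0.2) "low"
  else "very low"
}

#' Per-cell areas of a geographic grid
#'
#' Spherical-Earth cell areas in km^2: `area(row) = (pi/180 * R)^2 *
#' cell_size^2 * cos(lat_center(row))` with mean Earth radius
#' `R = 6371.0088 km`; constant within each latitude row.
#'
#' @param geom a `raster_grid` or geometry list (|lat| must stay within 90).
#' @return a `raster_grid` of km^2 per cell (all cells valid).
#' @export
cell_areas <- function(geom) {
  if (inherits(geom, "raster_grid")) geom <- grid_geometry(geom)
  lat_c <- geom$origin_lat - (seq_len(geom$n_rows) - 0.5) * geom$cell_size
  if (any(abs(lat_c) > 90))
    stop("cell_areas: latitude exceeds +/-90 degrees")
  R <- 6371.0088
  row_area <- (pi / 180 * R)^2 * geom$cell_size^2 * cos(lat_c * pi / 180)
  raster_grid(matrix(row_area, geom$n_rows, geom$n_cols),
              geom$origin_lon, geom$origin_lat, geom$cell_size)
}

#' Suitable area of a binary map
#'
#' Latitude-weighted area of the suitable (value 1) cells, optionally
#' restricted to a region, in units of 10^3 km^2.
#'
#' @param binary a binary `raster_grid` (0/1).
#' @param region_mask optional logical matrix or co-registered 0/1
#'   `raster_grid` marking the region.
#' @return numeric scalar, 10^3 km^2.
#' @export
suitable_area <- function(binary, region_mask = NULL) {
  areas <- cell_areas(binary)$values
  sel <- !binary$nodata_mask & binary$values == 1
  if (!is.null(region_mask)) {
    rm <- if (inherits(region_mask, "raster_grid")) {
      if (!same_geometry(binary, region_mask))
        stop("suitable_area: region mask geometry mismatch")
      !region_mask$nodata_mask & region_mask$values == 1
    } else as.matrix(region_mask)
    sel <- sel & rm
  }
  sum(areas[sel]) / 1000
}

#' Percent change in suitable area
#'
#' `(current - future) / current * 100`: positive values are reductions,
#' negative values expansions.
#'
#' @param current_area,future_area areas in the same units; `current_area`
#'   must be positive.
#' @return percent reduction.
#' @export
area_change <- function(current_area, future_area) {
  if (current_area <= 0)
    stop("area_change: current area must be positive")
  (current_area - future_area) / current_area * 100
}
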