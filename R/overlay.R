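#' Minimum-rule suitability overlay
#'
#' Cellwise minimum of co-registered suitability surfaces — the "barrel
#' effect" composition in which the least favourable factor determines joint
#' suitability. A cell is nodata when any input is nodata there.
#'
#' @param surfaces list of at least two co-registered `raster_grid` surfaces.
#' @return a `raster_grid`.
#' @export
min_overlay <- function(surfaces) {
  if (length(surfaces) < 2L) stop("min_overlay: need at least 2 surfaces")
  ref <- surfaces[[1L]]
  for (s in surfaces[-1L])
    if (!same_geometry(ref, s)) stop("min_overlay: geometry mismatch")
  vals <- do.call(pmin, lapply(surfaces, function(s) s$values))
  mask <- Reduce(`|`, lapply(surfaces, function(s) s$nodata_mask))
  vals[mask] <- NA_real_
  raster_grid(vals, ref$origin_lon, ref$origin_lat, ref$cell_size,
              nodata_mask = mask)
}

#' Host-constrained parasite suitability
#'
#' The parasite's final suitability is the per-cell minimum of its climate
#' suitability, its soil suitability and the host's final suitability: an
#' obligate parasite can only occur where environment and host coincide. By
#' construction the output never exceeds the host surface anywhere.
#'
#' @param parasite_climate,parasite_soil,host_final co-registered
#'   `raster_grid` suitability surfaces.
#' @return a `raster_grid`.
#' @export
host_constrained_suitability <- function(parasite_climate, parasite_soil,
                                         host_final) {
  min_overlay(list(parasite_climate, parasite_soil, host_final))
}

#' Binarize a suitability surface
#'
#' A cell is suitable (1) when its HSI is at or above the threshold; the
#' boundary always belongs to the suitable class.
#'
#' @param surface a `raster_grid` suitability surface.
#' @param threshold decision threshold in `(0, 1)`.
#' @return a `raster_grid` of 0/1 (class also `binary_map`) with attributes
#'   `threshold` and `provenance`.
#' @export
binarize <- function(surface, threshold) {
  if (threshold <= 0 || threshold >= 1)
    stop("binarize: threshold must lie in (0, 1)")
  vals <- ifelse(surface$values >= threshold, 1, 0)
  out <- raster_grid(vals, surface$origin_lon, surface$origin_lat,
                     surface$cell_size, nodata_mask = surface$nodata_mask,
                     is_categorical = TRUE)
  attr(out, "threshold") <- threshold
  attr(out, "provenance") <- list(rule = ">=", threshold = threshold)
  class(out) <- c("binary_map", class(out))
  out
}

#' Intersection of binary suitability maps
#'
#' Cellwise logical AND of co-registered 0/1 maps: the "co-suitable area"
#' where every constituent map agrees on suitability.
#'
#' @param binary_maps list of at least two co-registered binary maps.
#' @return a binary `raster_grid` (class `binary_map`).
#' @export
co_suitable_map <- function(binary_maps) {
  if (length(binary_maps) < 2L) stop("co_suitable_map: need at least 2 maps")
  ref <- binary_maps[[1L]]
  for (m in binary_maps[-1L])
    if (!same_geometry(ref, m)) stop("co_suitable_map: geometry mismatch")
  vals <- Reduce(function(a, b) a * b,
                 lapply(binary_maps, function(m) m$values))
  mask <- Reduce(`|`, lapply(binary_maps, function(m) m$nodata_mask))
  vals[mask] <- NA_real_
  out <- raster_grid(vals, ref$origin_lon, ref$origin_lat, ref$cell_size,
                     nodata_mask = mask, is_categorical = TRUE)
  attr(out, "provenance") <- list(rule = "and", n_maps = length(binary_maps))
  class(out) <- c("binary_map", class(out))
  out
}

#' Threshold sensitivity of the suitable area
#'
#' Recomputes the suitable area at the threshold perturbed by a relative
#' `delta` (default +/-5%) and reports absolute areas and changes relative to
#' the unperturbed threshold. Perturbed thresholds falling outside `(0, 1)`
#' are clipped with a warning.
#'
#' @param surface a `raster_grid` suitability surface.
#' @param threshold central threshold in `(0, 1)`.
#' @param delta relative perturbation (default 0.05).
#' @param region_mask optional logical matrix or binary `raster_grid`
#'   restricting the accounting to a region.
#' @return data.frame with columns `threshold`, `area` (10^3 km^2),
#'   `relative_change` (fraction vs the central threshold).
#' @export
threshold_sensitivity <- function(surface, threshold, delta = 0.05,
                                  region_mask = NULL) {
  ts <- threshold * c(1 - delta, 1, 1 + delta)
  clipped <- pmin(pmax(ts, 1e-9), 1 - 1e-9)
  if (any(clipped != ts))
    warning("threshold_sensitivity: perturbed threshold clipped into (0, 1)")
  areas <- vapply(clipped, function(t)
    suitable_area(binarize(surface, t), region_mask), numeric(1))
  data.frame(threshold = clipped, area = areas,
             relative_change = if (areas[2L] > 0) (areas - areas[2L]) / areas[2L]
                               else rep(NA_real_, 3L))
}
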