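#' Occurrence records
#'
#' Labelled point records: presences and pseudo-absences with coordinates and
#' a species identifier. Stored as a data.frame with columns
#' `species_id, lon, lat, label`; `label` takes only the values `"presence"`
#' and `"pseudo_absence"`.
#'
#' @param lon,lat numeric coordinate vectors in degrees.
#' @param label character vector, `"presence"` or `"pseudo_absence"`.
#' @param species_id character vector or scalar.
#' @return data.frame of class `occurrence_set`.
#' @export
occurrence_set <- function(lon = numeric(), lat = numeric(),
                           label = character(), species_id = character()) {
  n <- length(lon)
  if (length(lat) != n) stop("occurrence_set: lon/lat length mismatch")
  if (n > 0L) {
    if (length(label) == 1L) label <- rep(label, n)
    if (length(species_id) == 1L) species_id <- rep(species_id, n)
  }
  if (!all(label %in% c("presence", "pseudo_absence")))
    stop("occurrence_set: label must be 'presence' or 'pseudo_absence'")
  structure(data.frame(species_id = as.character(species_id),
                       lon = as.numeric(lon), lat = as.numeric(lat),
                       label = as.character(label),
                       stringsAsFactors = FALSE),
            class = c("occurrence_set", "data.frame"))
}

as_occurrence_set <- function(df) {
  occurrence_set(df$lon, df$lat, df$label, df$species_id)
}

#' Read/write occurrence CSV
#'
#' CSV with header `species_id,lon,lat,label`.
#' @param path file path.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "lon", "lat", "label")
  if (!all(need %in% names(df)))
    stop("read_occurrences: header must contain ", paste(need, collapse = ","))
  as_occurrence_set(df[need])
}

#' @rdname read_occurrences
#' @param points an `occurrence_set`.
#' @export
write_occurrences <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Thin occurrences to one record per grid cell
#'
#' Grid-based deduplication: within each species, at most one record is kept
#' per occupied cell of the reference grid, the survivor chosen uniformly at
#' random under `seed`. This is the standard 1-cell ("1 km grid") thinning
#' used to damp spatial sampling bias before niche modelling.
#'
#' @param points an [occurrence_set].
#' @param geom a `raster_grid` (or its geometry) defining the thinning grid.
#' @param seed integer seed for the per-cell random tie-break.
#' @return thinned `occurrence_set` (row order follows cell order per species).
#' @export
thin_occurrences <- function(points, geom, seed) {
  if (nrow(points) == 0L) return(points)
  ci <- cell_index(geom, points$lon, points$lat)
  keep <- integer(0)
  set.seed(as.integer(seed))
  for (sp in unique(points$species_id)) {
    rows <- which(points$species_id == sp)
    cells <- ci$cell[rows]
    for (cl in unique(cells)) {
      members <- rows[cells == cl]
      keep <- c(keep, if (length(members) == 1L) members
                else members[sample.int(length(members), 1L)])
    }
  }
  as_occurrence_set(points[sort(keep), , drop = FALSE])
}

#' Extract environmental values at points
#'
#' Looks up the containing cell's value in every stack layer for each point.
#' Points falling on a cell that is nodata in any layer are dropped; the drop
#' count and indices are attached as the `"dropped"` attribute.
#'
#' @param points an [occurrence_set].
#' @param stack an [env_stack].
#' @return data.frame with one column per layer plus `label`; attributes
#'   `"cells"` (row-major cell index per retained point) and `"dropped"`.
#' @export
extract_env <- function(points, stack) {
  geom <- stack_geometry(stack)
  ci <- cell_index(geom, points$lon, points$lat)
  idx <- cbind(ci$row, ci$col)
  tab <- as.data.frame(lapply(stack$layers, function(l) l$values[idx]))
  names(tab) <- names(stack$layers)
  ok <- stats::complete.cases(tab)
  if (!any(ok))
    stop("extract_env: all points fall on nodata cells")
  out <- tab[ok, , drop = FALSE]
  out$label <- points$label[ok]
  rownames(out) <- NULL
  attr(out, "cells") <- ci$cell[ok]
  attr(out, "dropped") <- list(n = sum(!ok), index = which(!ok))
  out
}
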