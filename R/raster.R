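#' Georeferenced raster grid
#'
#' The elementary spatial container of the package: a rectangular grid of
#' numeric values on a geographic (lon/lat, EPSG:4326-style) lattice with
#' square cells, a nodata mask, and a flag distinguishing continuous from
#' integer-coded categorical layers. Rows run north to south: row 1 is the
#' northernmost row and `origin_lat` is the latitude of the grid's upper-left
#' corner.
#'
#' @param values numeric matrix of cell values (row 1 = northernmost row).
#' @param origin_lon,origin_lat longitude/latitude of the upper-left corner,
#'   in decimal degrees.
#' @param cell_size cell edge length in degrees (square cells).
#' @param nodata_mask logical matrix, same shape as `values`; `TRUE` marks a
#'   nodata cell. Defaults to `is.na(values)`.
#' @param is_categorical logical; `TRUE` for integer-coded class layers
#'   (resampled by nearest neighbour, excluded from distance-based steps).
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin_lon, origin_lat, cell_size,
                        nodata_mask = NULL, is_categorical = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("raster_grid: grid must have at least one row and one column")
  if (!is.numeric(cell_size) || cell_size <= 0)
    stop("raster_grid: cell_size must be positive")
  if (is.null(nodata_mask)) nodata_mask <- is.na(values)
  nodata_mask <- as.matrix(nodata_mask)
  if (!identical(dim(nodata_mask), dim(values)))
    stop("raster_grid: nodata_mask shape must equal values shape")
  mode(nodata_mask) <- "logical"
  if (any(!is.finite(values[!nodata_mask])))
    stop("raster_grid: all valid-cell values must be finite")
  values[nodata_mask] <- NA_real_
  structure(
    list(values = values, origin_lon = origin_lon, origin_lat = origin_lat,
         cell_size = cell_size, nodata_mask = nodata_mask,
         is_categorical = isTRUE(is_categorical)),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d cells, %.6g deg/cell, origin (%.6g, %.6g)\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin_lon, x$origin_lat))
  cat(sprintf("  valid cells: %d/%d; %s\n", sum(!x$nodata_mask),
              length(x$values),
              if (x$is_categorical) "categorical" else "continuous"))
  invisible(x)
}

grid_geometry <- function(grid) {
  list(origin_lon = grid$origin_lon, origin_lat = grid$origin_lat,
       cell_size = grid$cell_size,
       n_rows = nrow(grid$values), n_cols = ncol(grid$values))
}

same_geometry <- function(a, b, tol = 1e-9) {
  ga <- grid_geometry(a); gb <- grid_geometry(b)
  ga$n_rows == gb$n_rows && ga$n_cols == gb$n_cols &&
    abs(ga$origin_lon - gb$origin_lon) < tol &&
    abs(ga$origin_lat - gb$origin_lat) < tol &&
    abs(ga$cell_size - gb$cell_size) < tol
}

#' Locate points on a grid
#'
#' Maps lon/lat points to 1-based (row, col) indices. Cells are treated as
#' boxes closed on their low-index edges, so a point lying exactly on a shared
#' edge belongs to the lower-index (western / northern) cell.
#'
#' @param geom a `raster_grid` or the result of its internal geometry accessor.
#' @param lon,lat numeric vectors of coordinates in degrees.
#' @return data.frame with columns `row`, `col`, `cell` (row-major 1-based).
#' @export
cell_index <- function(geom, lon, lat) {
  if (inherits(geom, "raster_grid")) geom <- grid_geometry(geom)
  xmax <- geom$origin_lon + geom$n_cols * geom$cell_size
  ymin <- geom$origin_lat - geom$n_rows * geom$cell_size
  out <- lon < geom$origin_lon - 1e-12 | lon > xmax + 1e-12 |
    lat > geom$origin_lat + 1e-12 | lat < ymin - 1e-12
  if (any(out))
    stop(sprintf("cell_index: %d point(s) fall outside the grid extent", sum(out)))
  col <- pmax(1L, as.integer(ceiling((lon - geom$origin_lon) / geom$cell_size)))
  row <- pmax(1L, as.integer(ceiling((geom$origin_lat - lat) / geom$cell_size)))
  col <- pmin(col, geom$n_cols); row <- pmin(row, geom$n_rows)
  data.frame(row = row, col = col, cell = (row - 1L) * geom$n_cols + col)
}

cell_center <- function(geom, row, col) {
  if (inherits(geom, "raster_grid")) geom <- grid_geometry(geom)
  list(lon = geom$origin_lon + (col - 0.5) * geom$cell_size,
       lat = geom$origin_lat - (row - 0.5) * geom$cell_size)
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text single-band raster I/O in the ESRI ASCII grid (`.asc`) format
#' used throughout the species-distribution-modelling toolchain. Integer
#' layers round-trip bit-exactly; continuous layers round-trip to better than
#' float32 precision.
#'
#' @param path file path.
#' @param categorical logical; mark the layer as integer-coded on read.
#' @return `read_raster` returns a `raster_grid`; `write_raster` invisibly
#'   returns `path`.
#' @export
read_raster <- function(path, categorical = FALSE) {
  if (!file.exists(path)) stop("read_raster: file not found: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L) stop("read_raster: malformed header line: ", ln)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("read_raster: header is missing ", paste(setdiff(need, names(hdr)), collapse = ", "))
  body <- scan(path, skip = 6L, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(body) != nr * nc)
    stop("read_raster: expected ", nr * nc, " values, found ", length(body))
  vals <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  mask <- vals == hdr$nodata_value
  vals[mask] <- NA_real_
  raster_grid(vals,
              origin_lon = hdr$xllcorner,
              origin_lat = hdr$yllcorner + nr * hdr$cellsize,
              cell_size = hdr$cellsize, nodata_mask = mask,
              is_categorical = categorical)
}

#' @rdname read_raster
#' @param grid a `raster_grid`.
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  nodata <- -9999
  if (any(grid$values[!grid$nodata_mask] == nodata, na.rm = TRUE))
    stop("write_raster: a valid cell equals the nodata sentinel -9999")
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.12g", grid$origin_lon),
           sprintf("yllcorner %.12g", grid$origin_lat - nr * grid$cell_size),
           sprintf("cellsize %.12g", grid$cell_size),
           sprintf("NODATA_value %d", nodata))
  vals <- grid$values
  vals[grid$nodata_mask] <- nodata
  fmt <- if (grid$is_categorical) "%d" else "%.10g"
  body <- apply(vals, 1L, function(r) {
    if (grid$is_categorical) r <- as.integer(round(r))
    paste(sprintf(fmt, r), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Co-registered environmental stack
#'
#' An ordered, named set of [raster_grid] layers sharing one geometry: the
#' predictor space every modelling stage works in.
#'
#' @param layers named list of `raster_grid` objects on identical geometry.
#' @return object of class `env_stack`.
#' @export
env_stack <- function(layers) {
  if (length(layers) == 0L) stop("env_stack: empty layer list")
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("env_stack: layers must have unique non-empty names")
  if (!all(vapply(layers, inherits, logical(1), "raster_grid")))
    stop("env_stack: all layers must be raster_grid objects")
  for (l in layers[-1L])
    if (!same_geometry(layers[[1L]], l))
      stop("env_stack: layers do not share one geometry")
  structure(list(layers = layers), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layers: %s\n", length(x$layers),
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

stack_geometry <- function(stack) grid_geometry(stack$layers[[1L]])

#' Valid-everywhere mask of a stack
#'
#' Logical matrix that is `TRUE` where every layer has data.
#' @param stack an `env_stack`.
#' @export
stack_valid_mask <- function(stack) {
  m <- !stack$layers[[1L]]$nodata_mask
  for (l in stack$layers[-1L]) m <- m & !l$nodata_mask
  m
}

#' Subset an environmental stack by layer name
#' @param stack an `env_stack`.
#' @param names character vector of layer names to keep.
#' @export
stack_subset <- function(stack, names) {
  missing <- setdiff(names, names(stack$layers))
  if (length(missing))
    stop("stack_subset: no such layer(s): ", paste(missing, collapse = ", "))
  env_stack(stack$layers[names])
}

#' Align raster layers onto a target geometry
#'
#' Resamples every layer onto the target grid: continuous layers by bilinear
#' interpolation between source cell centres, categorical layers by nearest
#' neighbour. A target cell becomes nodata whenever any contributing source
#' cell is nodata. Layers already on the target geometry pass through
#' unchanged.
#'
#' @param layers named list of `raster_grid` objects (any geometries).
#' @param target a `raster_grid` (or geometry list) defining the output grid.
#' @return an [env_stack] on the target geometry.
#' @export
align_stack <- function(layers, target) {
  if (length(layers) == 0L) stop("align_stack: empty layer list")
  geom <- if (inherits(target, "raster_grid")) grid_geometry(target) else target
  out <- lapply(layers, function(l) {
    if (inherits(target, "raster_grid") && same_geometry(l, target)) return(l)
    resample_grid(l, geom)
  })
  env_stack(out)
}

resample_grid <- function(src, geom) {
  # target cell centres
  lon <- geom$origin_lon + (seq_len(geom$n_cols) - 0.5) * geom$cell_size
  lat <- geom$origin_lat - (seq_len(geom$n_rows) - 0.5) * geom$cell_size
  sg <- grid_geometry(src)
  # fractional position in source cell-centre coordinates
  gx <- (rep(lon, each = geom$n_rows) - sg$origin_lon) / sg$cell_size - 0.5
  gy <- (sg$origin_lat - rep(lat, times = geom$n_cols)) / sg$cell_size - 0.5
  if (all(gx < -0.5 | gx > sg$n_cols - 0.5) || all(gy < -0.5 | gy > sg$n_rows - 0.5))
    stop("align_stack: source layer does not overlap the target extent")
  if (src$is_categorical) {
    ri <- pmin(pmax(as.integer(round(gy)) + 1L, 1L), sg$n_rows)
    ci <- pmin(pmax(as.integer(round(gx)) + 1L, 1L), sg$n_cols)
    v <- src$values[cbind(ri, ci)]
    vals <- matrix(v, nrow = geom$n_rows, ncol = geom$n_cols)
    return(raster_grid(vals, geom$origin_lon, geom$origin_lat, geom$cell_size,
                       nodata_mask = is.na(vals), is_categorical = TRUE))
  }
  c0 <- pmin(pmax(as.integer(floor(gx)) + 1L, 1L), sg$n_cols)
  c1 <- pmin(c0 + 1L, sg$n_cols)
  r0 <- pmin(pmax(as.integer(floor(gy)) + 1L, 1L), sg$n_rows)
  r1 <- pmin(r0 + 1L, sg$n_rows)
  fx <- pmin(pmax(gx - (c0 - 1L), 0), 1)
  fy <- pmin(pmax(gy - (r0 - 1L), 0), 1)
  v00 <- src$values[cbind(r0, c0)]; v01 <- src$values[cbind(r0, c1)]
  v10 <- src$values[cbind(r1, c0)]; v11 <- src$values[cbind(r1, c1)]
  v <- (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
  # nodata propagation: any contributing nodata corner poisons the cell
  v[is.na(v00) | is.na(v01) | is.na(v10) | is.na(v11)] <- NA_real_
  vals <- matrix(v, nrow = geom$n_rows, ncol = geom$n_cols)
  raster_grid(vals, geom$origin_lon, geom$origin_lat, geom$cell_size,
              nodata_mask = is.na(vals), is_categorical = FALSE)
}
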