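#' Tile a grid into contiguous rectangular blocks
#'
#' Regular square tiling; edge blocks may be smaller. Block ids are assigned
#' row-major from 0, so a cell at 0-based (row, col) belongs to block
#' `floor(row/bs) * nBlockCols + floor(col/bs)`.
#'
#' @param geom a `raster_grid` or geometry list.
#' @param block_size_cells block edge length in cells (>= 1).
#' @return integer `raster_grid` of block ids (categorical).
#' @export
make_blocks <- function(geom, block_size_cells) {
  if (inherits(geom, "raster_grid")) geom <- grid_geometry(geom)
  bs <- as.integer(block_size_cells)
  if (bs < 1L) stop("make_blocks: block_size_cells must be >= 1")
  if (bs > max(geom$n_rows, geom$n_cols))
    warning("make_blocks: block size exceeds the grid; a single block results")
  nbc <- ceiling(geom$n_cols / bs)
  row0 <- matrix(seq_len(geom$n_rows) - 1L, geom$n_rows, geom$n_cols)
  col0 <- matrix(seq_len(geom$n_cols) - 1L, geom$n_rows, geom$n_cols,
                 byrow = TRUE)
  ids <- (row0 %/% bs) * nbc + (col0 %/% bs)
  raster_grid(ids, geom$origin_lon, geom$origin_lat, geom$cell_size,
              is_categorical = TRUE)
}

#' Repeated 70/30 block-level train/validation splits
#'
#' Per iteration, a fresh seeded permutation assigns `round(train_frac * B)`
#' blocks (round half up) to training and the rest to validation; points are
#' later assigned to partitions through their cell's block id, so the two
#' partitions are spatially disjoint by construction.
#'
#' @param block_grid integer `raster_grid` of block ids from [make_blocks].
#' @param train_frac fraction of blocks assigned to training (default 0.7).
#' @param n_iterations number of repeated splits (default 10).
#' @param seed integer; iteration `i` uses seed `seed + i`.
#' @return object of class `cv_plan`: list with `block_grid` and
#'   `iterations`, each iteration a list of `train` ids, `valid` ids, `seed`.
#' @export
split_blocks <- function(block_grid, train_frac = 0.7, n_iterations = 10,
                         seed = 1) {
  ids <- sort(unique(block_grid$values[!block_grid$nodata_mask]))
  if (length(ids) < 2L)
    stop("split_blocks: need at least 2 blocks to split")
  n_train <- as.integer(floor(train_frac * length(ids) + 0.5))
  n_train <- min(max(n_train, 1L), length(ids) - 1L)
  iterations <- lapply(seq_len(n_iterations), function(i) {
    it_seed <- as.integer(seed) + i
    set.seed(it_seed)
    perm <- sample(ids)
    list(train = sort(perm[seq_len(n_train)]),
         valid = sort(perm[-seq_len(n_train)]),
         seed = it_seed)
  })
  structure(list(block_grid = block_grid, iterations = iterations,
                 train_frac = train_frac),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  b <- length(unique(x$block_grid$values[!x$block_grid$nodata_mask]))
  cat(sprintf("<cv_plan> %d blocks, %d iterations, %d/%d train/valid\n",
              b, length(x$iterations),
              length(x$iterations[[1L]]$train),
              length(x$iterations[[1L]]$valid)))
  invisible(x)
}
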