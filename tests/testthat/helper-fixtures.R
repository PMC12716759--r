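# shared in-code fixtures; everything is generated, nothing read from disk

# plain grid with simple georeference; values filled column-major from v
mk_grid <- function(v, nr, nc, origin_lon = 100, origin_lat = 45,
                    cell_size = 0.1, categorical = FALSE) {
  raster_grid(matrix(v, nr, nc), origin_lon, origin_lat, cell_size,
              is_categorical = categorical)
}

# random continuous grid under a seed
random_grid <- function(nr, nc, seed, ...) {
  set.seed(seed)
  mk_grid(runif(nr * nc), nr, nc, ...)
}

# small landscape + presences used by several modules
small_landscape <- function(seed = 3, nr = 40, nc = 40, n_pres = 120,
                            autocorr = 4) {
  cfg <- landscape_config(n_rows = nr, n_cols = nc,
                          autocorr_length = autocorr, seed = seed)
  ls <- generate_landscape(cfg)
  pres <- sample_occurrences(ls$truth$host_final_truth, n_pres,
                             seed = seed + 1, species_id = "host")
  list(cfg = cfg, stack = ls$stack, truth = ls$truth, presences = pres)
}

# a two-blob environment: left half cold, right half hot, presences left only
blob_stack <- function(nr = 10, nc = 10) {
  v <- matrix(0, nr, nc)
  v[, (nc / 2 + 1):nc] <- 10
  env_stack(list(temp = mk_grid(v, nr, nc)))
}

blob_presences <- function(stack, n = 12, seed = 1) {
  set.seed(seed)
  g <- stack$layers[[1L]]
  cs <- g$cell_size
  # random positions inside the left (value 0) half
  col <- sample.int(ncol(g$values) / 2, n, replace = TRUE)
  row <- sample.int(nrow(g$values), n, replace = TRUE)
  occurrence_set(g$origin_lon + (col - runif(n)) * cs,
                 g$origin_lat - (row - runif(n)) * cs,
                 "presence", "sp")
}

expect_grid_equal <- function(a, b, tol = 0) {
  expect_true(same_geometry_for_tests(a, b))
  if (tol == 0) expect_identical(unname(a$values), unname(b$values))
  else expect_lt(max(abs(a$values - b$values), na.rm = TRUE), tol)
  expect_identical(a$nodata_mask, b$nodata_mask)
}

same_geometry_for_tests <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$origin_lon, a$origin_lat, a$cell_size),
                     c(b$origin_lon, b$origin_lat, b$cell_size)))
}
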