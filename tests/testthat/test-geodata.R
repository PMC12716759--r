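test_that("ASCII grid round-trip preserves integer values, mask and georeference", {
  set.seed(11)
  v <- matrix(sample.int(9L, 100, replace = TRUE), 10, 10)
  v[2, 3] <- NA; v[7, 9] <- NA
  g <- raster_grid(v, origin_lon = 100, origin_lat = 45, cell_size = 0.1,
                   is_categorical = TRUE)
  path <- withr::local_tempfile(fileext = ".asc")
  write_raster(g, path)
  r <- read_raster(path, categorical = TRUE)
  expect_identical(unname(r$values), unname(g$values))
  expect_identical(r$nodata_mask, g$nodata_mask)
  expect_equal(r$origin_lon, g$origin_lon)
  expect_equal(r$origin_lat, g$origin_lat)
  expect_equal(r$cell_size, g$cell_size)
  expect_true(r$is_categorical)
})

test_that("an all-nodata grid reads back with zero valid cells", {
  g <- raster_grid(matrix(NA_real_, 4, 5), 0, 10, 0.5)
  path <- withr::local_tempfile(fileext = ".asc")
  write_raster(g, path)
  r <- read_raster(path)
  expect_equal(sum(!r$nodata_mask), 0)
})

test_that("continuous round-trip error stays at float32-epsilon scale", {
  set.seed(42)
  g <- mk_grid(rnorm(400), 20, 20)
  path <- withr::local_tempfile(fileext = ".asc")
  write_raster(g, path)
  r <- read_raster(path)
  expect_lt(max(abs(r$values - g$values) / pmax(abs(g$values), 1)), 1.2e-7)
})

test_that("malformed raster files are rejected with a format error", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 3", "nrows nonsense"), path)
  expect_error(suppressWarnings(read_raster(path)), "header")
})

test_that("align_stack passes through layers already on the target geometry", {
  g <- random_grid(8, 8, seed = 1)
  st <- align_stack(list(a = g), target = g)
  expect_identical(st$layers$a$values, g$values)
})

test_that("align_stack preserves constant layers at any resolution", {
  src <- mk_grid(rep(3.5, 16), 4, 4, cell_size = 0.2)
  target <- mk_grid(rep(0, 64), 8, 8, cell_size = 0.1)
  st <- align_stack(list(c = src), target)
  expect_true(all(abs(st$layers$c$values - 3.5) < 1e-12))
})

test_that("bilinear upsampling matches the hand-computed corner blend", {
  # 2x2 source with corners 0,10 (top), 20,40 (bottom); centres at 0.05 off
  src <- raster_grid(matrix(c(0, 20, 10, 40), 2, 2), 0, 0.2, 0.1)
  target <- raster_grid(matrix(0, 4, 4), 0, 0.2, 0.05)
  st <- align_stack(list(z = src), target)
  # target cell (2,2) centre (0.075, 0.125): fractional (0.25, 0.25) between
  # source centres -> (1-.25)(1-.25)*0 + .25*.75*10 + .75*.25*20 + .25*.25*40
  expect_equal(st$layers$z$values[2, 2],
               0.75 * 0.75 * 0 + 0.25 * 0.75 * 10 + 0.75 * 0.25 * 20 +
                 0.25 * 0.25 * 40)
})

test_that("nearest-neighbour alignment never invents categorical codes", {
  set.seed(5)
  src <- mk_grid(sample(c(2L, 5L, 9L), 36, replace = TRUE), 6, 6,
                 cell_size = 0.15, categorical = TRUE)
  target <- mk_grid(rep(0, 81), 9, 9, cell_size = 0.1)
  st <- align_stack(list(soil = src), target)
  expect_true(all(st$layers$soil$values %in% c(2, 5, 9)))
})

test_that("thinning keeps one record per occupied cell", {
  g <- mk_grid(rep(0, 100), 10, 10)
  # two points in the same cell plus one elsewhere
  pts <- occurrence_set(lon = c(100.01, 100.02, 100.55),
                        lat = c(44.99, 44.98, 44.55),
                        label = "presence", species_id = "sp")
  th <- thin_occurrences(pts, g, seed = 1)
  expect_equal(nrow(th), 2)
  # all in distinct cells -> no-op
  pts2 <- occurrence_set(lon = 100.05 + 0.1 * (0:4), lat = rep(44.95, 5),
                         label = "presence", species_id = "sp")
  expect_equal(nrow(thin_occurrences(pts2, g, seed = 1)), 5)
})

test_that("thinned count equals brute-force occupied-cell count and is idempotent", {
  set.seed(99)
  g <- mk_grid(rep(0, 400), 20, 20, origin_lon = 0, origin_lat = 20,
               cell_size = 1)
  n <- 1000
  pts <- occurrence_set(lon = runif(n, 0, 20), lat = runif(n, 0, 20),
                        label = "presence", species_id = "sp")
  th <- thin_occurrences(pts, g, seed = 7)
  # brute-force occupancy oracle
  occupied <- unique(paste(ceiling(20 - pts$lat), ceiling(pts$lon)))
  expect_equal(nrow(th), length(occupied))
  th2 <- thin_occurrences(th, g, seed = 8)
  expect_equal(nrow(th2), nrow(th))
  expect_setequal(paste(th2$lon, th2$lat), paste(th$lon, th$lat))
})

test_that("extract_env returns containing-cell values and reports nodata drops", {
  v <- matrix(7.5, 5, 5)
  g <- mk_grid(v, 5, 5)
  g$values[3, 3] <- NA; g$nodata_mask[3, 3] <- TRUE
  st <- env_stack(list(bio = g))
  pts <- occurrence_set(lon = c(100.05, 100.15), lat = c(44.95, 44.85),
                        label = "presence", species_id = "sp")
  tab <- extract_env(pts, st)
  expect_equal(tab$bio, c(7.5, 7.5))
  # a point on a nodata cell is dropped and counted
  g2 <- mk_grid(matrix(1, 5, 5), 5, 5)
  g2$values[1, 3] <- NA; g2$nodata_mask[1, 3] <- TRUE
  st2 <- env_stack(list(bio = g2))
  tab2 <- extract_env(occurrence_set(c(100.25, 100.05), c(44.95, 44.55),
                                     "presence", "sp"), st2)
  expect_equal(nrow(tab2), 1)
  expect_equal(attr(tab2, "dropped")$n, 1)
  expect_error(extract_env(occurrence_set(100.25, 44.95, "presence", "sp"),
                           st2), "nodata")
})

test_that("extract_env agrees with a brute-force nearest-cell oracle", {
  set.seed(21)
  nr <- 12; nc <- 15
  g1 <- mk_grid(rnorm(nr * nc), nr, nc, origin_lon = 10, origin_lat = 5,
                cell_size = 0.25)
  g2 <- mk_grid(runif(nr * nc), nr, nc, origin_lon = 10, origin_lat = 5,
                cell_size = 0.25)
  st <- env_stack(list(a = g1, b = g2))
  n <- 50
  lon <- runif(n, 10, 10 + nc * 0.25); lat <- runif(n, 5 - nr * 0.25, 5)
  pts <- occurrence_set(lon, lat, "presence", "sp")
  tab <- extract_env(pts, st)
  for (i in seq_len(n)) {
    r <- ceiling((5 - lat[i]) / 0.25); c <- ceiling((lon[i] - 10) / 0.25)
    expect_equal(tab$a[i], g1$values[r, c])
    expect_equal(tab$b[i], g2$values[r, c])
  }
})

test_that("thinned points yield unique cell indices in extract_env", {
  lsd <- small_landscape(seed = 8, nr = 20, nc = 20, n_pres = 200)
  th <- thin_occurrences(lsd$presences, lsd$stack$layers[[1]], seed = 3)
  tab <- extract_env(th, lsd$stack)
  expect_false(anyDuplicated(attr(tab, "cells")) > 0)
})
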