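test_that("profile envelope marks environmentally dissimilar cells eligible", {
  st <- blob_stack()
  pres <- blob_presences(st, n = 12, seed = 1)
  em <- environmental_profile_mask(st, pres)
  g <- st$layers$temp$values
  # presences all at value 0 -> the value-10 half is eligible
  expect_true(all(em$mask[g == 10]))
  pres_cells <- cell_index(st$layers$temp, pres$lon, pres$lat)
  expect_false(any(em$mask[cbind(pres_cells$row, pres_cells$col)]))
})

test_that("profile eligibility equals a brute-force per-cell envelope test", {
  set.seed(12)
  nr <- 30; nc <- 30
  l1 <- mk_grid(rnorm(nr * nc), nr, nc)
  l2 <- mk_grid(runif(nr * nc), nr, nc)
  st <- env_stack(list(a = l1, b = l2))
  pres <- occurrence_set(
    lon = 100 + runif(40, 0, nc * 0.1), lat = 45 - runif(40, 0, nr * 0.1),
    label = "presence", species_id = "sp")
  em <- environmental_profile_mask(st, pres, c(0.05, 0.95))
  pc <- cell_index(l1, pres$lon, pres$lat)
  q1 <- quantile(l1$values[cbind(pc$row, pc$col)], c(0.05, 0.95), names = FALSE)
  q2 <- quantile(l2$values[cbind(pc$row, pc$col)], c(0.05, 0.95), names = FALSE)
  manual <- !((l1$values >= q1[1] & l1$values <= q1[2]) &
              (l2$values >= q2[1] & l2$values <= q2[2]))
  manual[cbind(pc$row, pc$col)] <- FALSE
  expect_identical(em$mask, manual)
})

test_that("k-means flags the presence-free environmental blob in every run", {
  st <- blob_stack()
  pres <- blob_presences(st, n = 15, seed = 2)
  em <- kmeans_eligibility(st, pres, k = 2, runs = 5, seed = 3)
  g <- st$layers$temp$values
  expect_true(all(em$mask[g == 10]))
  expect_false(any(em$mask[g == 0]))
})

test_that("a single k-means run reduces the majority vote to that run", {
  lsd <- small_landscape(seed = 6, nr = 20, nc = 20, n_pres = 60)
  one <- kmeans_eligibility(lsd$stack, lsd$presences, k = 4, runs = 1, seed = 5)
  # replay oracle: rerun the same seeded clustering sequence by hand
  cont <- lsd$stack$layers[!vapply(lsd$stack$layers,
                                   function(l) l$is_categorical, logical(1))]
  vidx <- which(Reduce(`&`, lapply(lsd$stack$layers,
                                   function(l) !l$nodata_mask)))
  X <- vapply(cont, function(l) scale(l$values[vidx])[, 1],
              numeric(length(vidx)))
  pc <- cell_index(lsd$stack$layers[[1]], lsd$presences$lon, lsd$presences$lat)
  plin <- (pc$col - 1L) * 20L + pc$row
  set.seed(5 + 1)
  km <- kmeans(X, centers = 4, nstart = 1, iter.max = 100)
  dens <- tabulate(km$cluster[match(plin, vidx)], nbins = 4) / km$size
  flagged <- dens <= quantile(dens, 0.25, names = FALSE)
  manual <- matrix(FALSE, 20, 20)
  manual[vidx[flagged[km$cluster]]] <- TRUE
  manual[cbind(pc$row, pc$col)] <- FALSE
  expect_identical(one$mask, manual)
})

test_that("flat sampling returns the whole intersection when it is exactly n", {
  m <- matrix(FALSE, 6, 6); m[2, c(2, 4, 6)] <- TRUE
  em <- eligibility_mask(m, mk_grid(rep(0, 36), 6, 6))
  pts <- sample_pseudo_absences(em, n = 3, seed = 1)
  expect_equal(nrow(pts), 3)
  ci <- cell_index(mk_grid(rep(0, 36), 6, 6), pts$lon, pts$lat)
  expect_setequal(ci$col, c(2, 4, 6))
  expect_true(all(pts$label == "pseudo_absence"))
  expect_error(sample_pseudo_absences(em, n = 4, seed = 1), "eligible")
})

test_that("per-block sampling matches the requested presence counts per block", {
  g <- mk_grid(rep(0, 100), 10, 10)
  bg <- make_blocks(g, 5)  # 4 blocks of 25
  em <- eligibility_mask(matrix(TRUE, 10, 10), g)
  counts <- c("0" = 3, "1" = 7)
  pts <- sample_pseudo_absences(em, seed = 2,
                                block_assignment = list(block_grid = bg,
                                                        counts = counts))
  ci <- cell_index(g, pts$lon, pts$lat)
  got <- table(bg$values[cbind(ci$row, ci$col)])
  expect_equal(unname(got[c("0", "1")]), as.table(c(3L, 7L)),
               ignore_attr = TRUE)
  expect_equal(attr(pts, "block"), c(rep(0L, 3), rep(1L, 7)))
})

test_that("sampled pseudo-absences avoid presence cells (brute-force check)", {
  lsd <- small_landscape(seed = 10, nr = 25, nc = 25, n_pres = 80)
  prof <- environmental_profile_mask(lsd$stack, lsd$presences)
  km <- kmeans_eligibility(lsd$stack, lsd$presences, k = 4, runs = 3, seed = 4)
  pts <- sample_pseudo_absences(list(prof, km),
                                n = min(30, sum(prof$mask & km$mask)), seed = 6)
  g <- lsd$stack$layers[[1]]
  pa_cells <- cell_index(g, pts$lon, pts$lat)$cell
  pr_cells <- cell_index(g, lsd$presences$lon, lsd$presences$lat)$cell
  expect_length(intersect(pa_cells, pr_cells), 0)
})

test_that("the dual filter is at least as restrictive as either filter alone", {
  for (s in 1:3) {
    lsd <- small_landscape(seed = 20 + s, nr = 25, nc = 25, n_pres = 70)
    prof <- environmental_profile_mask(lsd$stack, lsd$presences)
    km <- kmeans_eligibility(lsd$stack, lsd$presences, k = 5, runs = 3,
                             seed = 30 + s)
    dual <- sum(prof$mask & km$mask)
    expect_lte(dual, min(sum(prof$mask), sum(km$mask)))
  }
})
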