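test_that("confusion rates match hand-computed tables", {
  # 4-point hand case
  cr <- confusion_rates(c(0.9, 0.8, 0.4, 0.1), c(1, 0, 1, 0), 0.5)
  expect_equal(cr$sensitivity, 0.5)
  expect_equal(cr$specificity, 0.5)
  expect_equal(cr$precision, 0.5)
  # perfect separation
  cr2 <- confusion_rates(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(unlist(cr2), c(sensitivity = 1, specificity = 1, precision = 1))
  # all predicted positive
  cr3 <- confusion_rates(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0), 0.1)
  expect_equal(cr3$sensitivity, 1)
  expect_equal(cr3$specificity, 0)
  # no predicted positive -> precision undefined
  cr4 <- confusion_rates(c(0.1, 0.2), c(1, 0), 0.9)
  expect_true(is.na(cr4$precision))
})

test_that("AUC equals the pairwise Mann-Whitney probability", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1)
  # O(n^2) oracle with half-credit ties on 50 random points
  set.seed(14)
  scores <- round(runif(50), 1)  # rounding forces ties
  labels <- rbinom(50, 1, 0.5)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  oracle <- mean(outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b)))
  expect_equal(roc_auc(scores, labels), oracle)
  # agreement with an established implementation
  expect_equal(roc_auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
  # monotone transform invariance
  expect_equal(roc_auc(qlogis(pmin(pmax(scores, 0.01), 0.99)), labels),
               roc_auc(pmin(pmax(scores, 0.01), 0.99), labels))
  expect_error(roc_auc(scores, rep(1, 50)), "both classes")
})

test_that("random scores give AUC near one half", {
  set.seed(8)
  scores <- runif(2000); labels <- rbinom(2000, 1, 0.5)
  expect_lt(abs(roc_auc(scores, labels) - 0.5), 0.05)
})

test_that("optimal threshold maximizes sensitivity + specificity, lowest on ties", {
  # separable: every threshold in the gap is optimal; lowest observed wins
  expect_equal(optimal_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 0.8)
  # exhaustive oracle on random data
  set.seed(3)
  scores <- runif(60); labels <- rbinom(60, 1, 0.4)
  cand <- sort(unique(scores))
  ss <- sapply(cand, function(t) {
    cr <- confusion_rates(scores, labels, t)
    cr$sensitivity + cr$specificity
  })
  got <- optimal_threshold(scores, labels)
  expect_equal(got, min(cand[ss >= max(ss) - 1e-12]))
  # duplicating points leaves the optimum unchanged
  expect_equal(optimal_threshold(rep(scores, 2), rep(labels, 2)), got)
})

test_that("Boyce is positive for suitability-driven presences and near zero under uniform sampling", {
  driven <- numeric(5)
  for (s in 1:5) {
    ls <- generate_landscape(landscape_config(n_rows = 60, n_cols = 60,
                                              seed = 40 + s))
    truth <- ls$truth$climate_truth_host
    pts <- sample_occurrences(truth, 300, seed = 50 + s)
    driven[s] <- boyce_index(truth, pts)
  }
  expect_true(all(driven > 0.5))
  nulls <- numeric(10)
  for (s in 1:10) {
    ls <- generate_landscape(landscape_config(n_rows = 60, n_cols = 60,
                                              seed = 60 + s))
    truth <- ls$truth$climate_truth_host
    set.seed(70 + s)
    g <- grid <- truth
    pts <- occurrence_set(lon = runif(300, g$origin_lon, g$origin_lon + 60 * g$cell_size),
                          lat = runif(300, g$origin_lat - 60 * g$cell_size, g$origin_lat),
                          label = "presence", species_id = "sp")
    nulls[s] <- boyce_index(truth, pts)
  }
  expect_lt(abs(mean(nulls)), 0.5)
})

test_that("Boyce is invariant under rank-preserving relabelling of the surface", {
  ls <- generate_landscape(landscape_config(n_rows = 40, n_cols = 40, seed = 77))
  truth <- ls$truth$climate_truth_host
  pts <- sample_occurrences(truth, 200, seed = 78)
  b1 <- boyce_index(truth, pts)
  squashed <- raster_grid(truth$values^3, truth$origin_lon, truth$origin_lat,
                          truth$cell_size)
  b2 <- boyce_index(squashed, pts)
  expect_equal(b1, b2)
})

test_that("metrics reports enforce the TSS identity and ranges", {
  r <- metrics_report(auc = 0.9, tss = 0.5, sensitivity = 0.8,
                      specificity = 0.7, precision = 0.75, boyce = 0.4,
                      threshold = 0.5, n_presence = 10, n_absence = 10)
  expect_equal(r$tss, r$sensitivity + r$specificity - 1)
  expect_error(metrics_report(auc = 0.9, tss = 0.6, sensitivity = 0.8,
                              specificity = 0.7, precision = 0.75,
                              boyce = 0.4, threshold = 0.5,
                              n_presence = 10, n_absence = 10), "TSS")
})
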