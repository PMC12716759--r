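test_that("single-feature attribution equals prediction minus base", {
  f <- function(d) plogis(2 * d[[1]])
  bg <- data.frame(a = rnorm(30))
  res <- exact_shapley(f, bg, c(a = 1.5))
  expect_equal(unname(res$phi["a"]), res$prediction - res$base_value)
})

test_that("ignored features get exactly zero attribution", {
  f <- function(d) 0.2 + 0.6 * (d$x > 0)
  set.seed(2)
  bg <- data.frame(x = rnorm(20), dummy = rnorm(20))
  res <- exact_shapley(f, bg, c(x = 1, dummy = 99))
  expect_identical(unname(res$phi["dummy"]), 0)
})

test_that("linear predictors recover the closed form b_i (x_i - mean(bg_i))", {
  set.seed(3)
  b <- c(0.5, -1.2, 2)
  f <- function(d) 0.1 + as.matrix(d) %*% b
  bg <- as.data.frame(matrix(rnorm(60), 20, 3))
  names(bg) <- c("f1", "f2", "f3")
  x <- c(f1 = 0.7, f2 = -0.4, f3 = 1.1)
  res <- exact_shapley(function(d) as.vector(f(d)), bg, x)
  expect_equal(unname(res$phi), unname(b * (x - colMeans(bg))),
               tolerance = 1e-10)
  expect_equal(res$base_value + sum(res$phi), res$prediction,
               tolerance = 1e-10)
})

test_that("subset enumeration matches the permutation-form oracle on nonlinear models", {
  set.seed(4)
  f <- function(d) plogis(d[[1]] * d[[2]] - d[[3]]^2 + 0.5 * d[[4]])
  bg <- as.data.frame(matrix(rnorm(10 * 4), 10, 4))
  names(bg) <- paste0("v", 1:4)
  x <- setNames(rnorm(4), names(bg))
  res <- exact_shapley(f, bg, x)
  oracle <- permutation_shapley(f, bg, x)
  expect_equal(res$phi, oracle, tolerance = 1e-10)
})

test_that("functionally interchangeable features share attribution on symmetric input", {
  f <- function(d) 0.3 * d[[1]] + 0.3 * d[[2]]
  bg <- data.frame(a = c(1, -1, 0.5, -0.5), b = c(1, -1, 0.5, -0.5))
  res <- exact_shapley(f, bg, c(a = 2, b = 2))
  expect_equal(unname(res$phi["a"]), unname(res$phi["b"]), tolerance = 1e-12)
})

test_that("efficiency holds for fitted ensemble members across samples", {
  set.seed(5)
  n <- 120
  tr <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  tr$label <- ifelse(tr$x1 + 0.5 * tr$x2 + rnorm(n, sd = 0.5) > 0,
                     "presence", "pseudo_absence")
  ens <- fit_ensemble(tr, default_ensemble_configs(11))
  bg <- tr[sample.int(n, 30), 1:3]
  samples <- tr[1:12, 1:3]
  mats <- lapply(ens$members, shap_matrix, background = bg, samples = samples)
  for (k in seq_along(mats)) {
    preds <- predict_prob(ens$members[[k]], samples)
    expect_lt(max(abs(mats[[k]]$base_value + rowSums(mats[[k]]$values) -
                      preds)), 1e-8)
  }
  esm <- ensemble_shap(mats)
  expect_lt(max(abs(esm$base_value + rowSums(esm$values) -
                    predict_prob(ens, samples))), 1e-8)
})

test_that("ensemble averaging of matrices is the point-wise mean", {
  base <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  mk <- function(v, bv, pr) structure(
    list(values = v, base_value = bv, predictions = pr,
         feature_names = c("a", "b", "c")), class = "shap_matrix")
  m <- mk(base, 0.4, rowSums(base) + 0.4)
  same <- ensemble_shap(list(m, m, m, m))
  expect_equal(same$values, m$values)
  expect_equal(same$base_value, m$base_value)
  neg <- mk(-base, -0.4, rowSums(-base) - 0.4)
  zero <- ensemble_shap(list(m, neg, m, neg))
  expect_true(all(abs(zero$values) < 1e-15))
})

test_that("global importance ranks dummies last and scales linearly", {
  v <- matrix(c(1, -2, 3, 0, 0, 0, 0.5, 0.5, -0.5), 3, 3,
              dimnames = list(NULL, c("big", "dead", "mid")))
  sm <- structure(list(values = v, base_value = 0, predictions = rowSums(v),
                       feature_names = c("big", "dead", "mid")),
                  class = "shap_matrix")
  gi <- global_importance(sm)
  expect_equal(gi$feature, c("big", "mid", "dead"))
  expect_equal(gi$mean_abs_shap[gi$feature == "dead"], 0)
  sm2 <- sm; sm2$values[, "mid"] <- 2 * sm2$values[, "mid"]
  gi2 <- global_importance(sm2)
  expect_equal(gi2$mean_abs_shap[gi2$feature == "mid"],
               2 * gi$mean_abs_shap[gi$feature == "mid"])
})

test_that("decision paths accumulate from base value to the prediction", {
  set.seed(6)
  f <- function(d) plogis(d[[1]] - 0.5 * d[[2]])
  bg <- data.frame(p = rnorm(15), q = rnorm(15))
  samples <- data.frame(p = rnorm(4), q = rnorm(4))
  sm <- shap_matrix(f, bg, samples)
  ex <- export_decision_and_dependence(sm, samples)
  last <- ex$decision[ex$decision$step == 2, ]
  expect_equal(last$cumulative, sm$predictions, tolerance = 1e-10)
  # recompute one path by hand
  imp_order <- rev(global_importance(sm)$feature)
  cum <- sm$base_value + cumsum(sm$values[1, imp_order])
  expect_equal(ex$decision$cumulative[ex$decision$sample == 1],
               unname(cum))
  one <- shap_matrix(f, bg, samples[1, , drop = FALSE])
  ex1 <- export_decision_and_dependence(one, samples[1, , drop = FALSE])
  expect_equal(unique(ex1$decision$sample), 1)
  expect_equal(nrow(ex$dependence), 4 * 2)
})

test_that("the truth's dominant climate driver ranks first in most seeds", {
  hits <- 0
  for (s in 1:5) {
    cfg <- landscape_config(n_rows = 30, n_cols = 30, autocorr_length = 3,
                            climate_effects = c(3, -0.6, 0.4, 0.3, 0),
                            seed = 600 + s)
    ls <- generate_landscape(cfg)
    pres <- sample_occurrences(ls$truth$climate_truth_host, 150,
                               seed = 700 + s)
    cs <- stack_subset(ls$stack, paste0("clim", 1:5))
    prof <- environmental_profile_mask(cs, pres)
    pa <- sample_pseudo_absences(prof, n = nrow(pres), seed = 800 + s)
    tab <- extract_env(bind_occurrences(pres, pa), cs)
    ens <- fit_ensemble(tab, default_ensemble_configs(900 + s))
    set.seed(950 + s)
    bg <- tab[sample.int(nrow(tab), 40), paste0("clim", 1:5)]
    samples <- tab[tab$label == "presence", paste0("clim", 1:5)][1:15, ]
    mats <- lapply(ens$members, shap_matrix, background = bg,
                   samples = samples)
    gi <- global_importance(ensemble_shap(mats))
    if (gi$feature[1] == "clim1") hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("enumeration refuses feature sets beyond the exact bound", {
  bg <- as.data.frame(matrix(rnorm(32), 2, 16))
  expect_error(exact_shapley(function(d) rowSums(d), bg,
                             setNames(rnorm(16), names(bg))),
               "bound")
})
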