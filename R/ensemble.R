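#' Configuration of one ensemble member
#'
#' The ensemble pairs two algorithms (random forest, gradient boosted trees)
#' at two complexity levels: "simple" members use shallow trees and large
#' leaves, "interm" members grow deeper trees and, for boosting, more rounds
#' at a smaller learning rate. Defaults per algorithm/complexity are supplied
#' when the corresponding argument is `NULL`.
#'
#' @param algorithm `"random_forest"` or `"gradient_boosted_trees"`.
#' @param complexity `"simple"` or `"interm"`.
#' @param trees number of trees / boosting rounds.
#' @param max_depth maximum tree depth (`0` = unlimited, random forest only).
#' @param min_leaf minimum terminal node size.
#' @param learning_rate shrinkage (gradient boosting only).
#' @param seed integer seed for the member's own randomness.
#' @return list of class `model_config`.
#' @export
model_config <- function(algorithm = c("random_forest", "gradient_boosted_trees"),
                         complexity = c("simple", "interm"),
                         trees = NULL, max_depth = NULL, min_leaf = NULL,
                         learning_rate = NULL, seed = 1) {
  algorithm <- match.arg(algorithm)
  complexity <- match.arg(complexity)
  defaults <- list(
    random_forest = list(
      simple = list(trees = 100, max_depth = 6, min_leaf = 10),
      interm = list(trees = 300, max_depth = 0, min_leaf = 2)),
    gradient_boosted_trees = list(
      simple = list(trees = 100, max_depth = 2, min_leaf = 10,
                    learning_rate = 0.1),
      interm = list(trees = 400, max_depth = 4, min_leaf = 2,
                    learning_rate = 0.05)))[[algorithm]][[complexity]]
  if (is.null(trees)) trees <- defaults$trees
  if (is.null(max_depth)) max_depth <- defaults$max_depth
  if (is.null(min_leaf)) min_leaf <- defaults$min_leaf
  if (algorithm == "gradient_boosted_trees") {
    if (is.null(learning_rate)) learning_rate <- defaults$learning_rate
  } else if (!is.null(learning_rate)) {
    stop("model_config: learning_rate applies to boosting only")
  }
  structure(list(algorithm = algorithm, complexity = complexity,
                 trees = trees, max_depth = max_depth, min_leaf = min_leaf,
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "model_config")
}

#' Default four-member ensemble configuration
#'
#' RF_simple, RF_interm, GBDT_simple, GBDT_interm.
#' @param seed base seed; members get distinct derived seeds.
#' @return named list of four [model_config] objects.
#' @export
default_ensemble_configs <- function(seed = 1) {
  list(rf_simple = model_config("random_forest", "simple", seed = seed + 11),
       rf_interm = model_config("random_forest", "interm", seed = seed + 22),
       gbdt_simple = model_config("gradient_boosted_trees", "simple", seed = seed + 33),
       gbdt_interm = model_config("gradient_boosted_trees", "interm", seed = seed + 44))
}

#' Fit one ensemble member
#'
#' @param config a [model_config].
#' @param train data.frame with numeric feature columns plus a `label` column
#'   (`"presence"`/`"pseudo_absence"`, or 0/1).
#' @return fitted member of class `niche_member` whose predictor maps a
#'   feature table to presence probabilities in `[0, 1]`.
#' @export
fit_member <- function(config, train) {
  stopifnot(inherits(config, "model_config"))
  y <- train_labels(train)
  if (length(unique(y)) < 2L)
    stop("fit_member: training data contain a single class")
  feats <- setdiff(names(train), "label")
  x <- train[feats]
  model <- if (config$algorithm == "random_forest") {
    ranger::ranger(x = x, y = factor(y, levels = c(0L, 1L)),
                   probability = TRUE, num.trees = config$trees,
                   max.depth = config$max_depth,
                   min.node.size = config$min_leaf,
                   importance = "impurity",
                   seed = config$seed, num.threads = 1)
  } else {
    xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = config$max_depth,
                    eta = config$learning_rate,
                    min_child_weight = config$min_leaf,
                    nthread = 1, seed = config$seed),
      data = xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1),
      nrounds = config$trees, verbose = 0)
  }
  structure(list(algorithm = config$algorithm, config = config,
                 model = model, feature_names = feats),
            class = "niche_member")
}

train_labels <- function(train) {
  if (!"label" %in% names(train)) stop("training table needs a 'label' column")
  l <- train$label
  if (is.numeric(l)) as.integer(l) else as.integer(l == "presence")
}

#' Predict presence probabilities from a member or ensemble
#'
#' @param object a `niche_member` or `niche_ensemble`.
#' @param newdata data.frame (or matrix) containing the model's features.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(object, newdata) UseMethod("predict_prob")

#' @export
predict_prob.niche_member <- function(object, newdata) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing))
    stop("predict_prob: missing feature(s): ", paste(missing, collapse = ", "))
  x <- newdata[object$feature_names]
  if (object$algorithm == "random_forest") {
    p <- stats::predict(object$model, data = x, num.threads = 1)$predictions
    unname(p[, "1"])
  } else {
    stats::predict(object$model, xgboost::xgb.DMatrix(as.matrix(x), nthread = 1))
  }
}

#' @export
predict_prob.niche_ensemble <- function(object, newdata) {
  p <- vapply(object$members, predict_prob, numeric(nrow(as.data.frame(newdata))),
              newdata = newdata)
  rowMeans(as.matrix(p))
}

#' Fit the four-member ensemble
#'
#' @param train training table (see [fit_member]).
#' @param configs list of [model_config]s (default [default_ensemble_configs]).
#' @return object of class `niche_ensemble` averaging member probabilities.
#' @export
fit_ensemble <- function(train, configs = default_ensemble_configs()) {
  members <- lapply(configs, fit_member, train = train)
  structure(list(members = members,
                 feature_names = members[[1L]]$feature_names,
                 configs = configs),
            class = "niche_ensemble")
}

#' Predict a suitability surface over a stack
#'
#' Evaluates the model on every cell that is valid in all required layers;
#' other cells are nodata.
#'
#' @param object a fitted `niche_member` or `niche_ensemble`.
#' @param stack an [env_stack] containing all model features as layers.
#' @return a `raster_grid` suitability surface with values in `[0, 1]`.
#' @export
predict_surface <- function(object, stack) {
  feats <- object$feature_names
  missing <- setdiff(feats, names(stack$layers))
  if (length(missing))
    stop("predict_surface: stack lacks feature layer(s): ",
         paste(missing, collapse = ", "))
  sub <- stack$layers[feats]
  ok <- Reduce(`&`, lapply(sub, function(l) !l$nodata_mask))
  newdata <- as.data.frame(lapply(sub, function(l) l$values[ok]))
  geom <- stack_geometry(stack)
  vals <- matrix(NA_real_, geom$n_rows, geom$n_cols)
  vals[ok] <- predict_prob(object, newdata)
  raster_grid(vals, geom$origin_lon, geom$origin_lat, geom$cell_size,
              nodata_mask = !ok)
}

bind_occurrences <- function(...) {
  as_occurrence_set(do.call(rbind, lapply(list(...), as.data.frame)))
}

#' Repeated spatially blocked training and prediction
#'
#' The core model-building loop: for each cross-validation iteration,
#' balanced pseudo-absences are drawn inside the iteration's training and
#' validation blocks (matching per-block presence counts from the eligibility
#' masks), the four-member ensemble is fitted on the training partition,
#' evaluated on the validation partition (AUC, optimal threshold,
#' sensitivity/specificity/precision, TSS, Boyce on validation presences),
#' and a full suitability surface is predicted. The final surface is the
#' cellwise mean over completed iterations and the binarization threshold is
#' the mean of the per-iteration optimal thresholds.
#'
#' @param stack an [env_stack] of predictor layers.
#' @param presences presence [occurrence_set] (already thinned).
#' @param cvplan a `cv_plan` from [split_blocks].
#' @param masks list of eligibility masks (see [environmental_profile_mask],
#'   [kmeans_eligibility]) intersected for pseudo-absence sampling.
#' @param configs ensemble member configurations.
#' @param seed integer; every iteration derives its own sub-seeds.
#' @param keep_ensembles keep fitted ensembles (needed for scenario
#'   projection and Shapley attribution).
#' @return list of class `iteration_result`: `surface` (mean suitability),
#'   `iteration_metrics` (list of [metrics_report]), `thresholds`,
#'   `mean_threshold`, `ensembles`, `n_completed`, `skipped`.
#' @export
run_iterations <- function(stack, presences, cvplan, masks, configs = NULL,
                           seed = 1, keep_ensembles = TRUE) {
  if (is.null(configs)) configs <- default_ensemble_configs(seed)
  if (sum(presences$label == "presence") < 10L)
    stop("run_iterations: need at least 10 presences")
  block_grid <- cvplan$block_grid
  ci <- cell_index(block_grid, presences$lon, presences$lat)
  pres_block <- block_grid$values[cbind(ci$row, ci$col)]
  surfaces <- list(); metrics <- list(); thresholds <- numeric(0)
  ensembles <- list(); skipped <- integer(0)
  for (it in seq_along(cvplan$iterations)) {
    iter <- cvplan$iterations[[it]]
    in_train <- pres_block %in% iter$train
    in_valid <- pres_block %in% iter$valid
    if (sum(in_train) < 2L || sum(in_valid) < 1L) {
      warning("run_iterations: iteration ", it,
              " lacks presences in a partition; skipped")
      skipped <- c(skipped, it)
      next
    }
    pa_train <- tryCatch(sample_pseudo_absences(
      masks, seed = iter$seed * 2L + 1L,
      block_assignment = list(block_grid = block_grid,
                              counts = table(pres_block[in_train])),
      redistribute = TRUE), error = function(e) NULL)
    pa_valid <- tryCatch(sample_pseudo_absences(
      masks, seed = iter$seed * 2L + 2L,
      block_assignment = list(block_grid = block_grid,
                              counts = table(pres_block[in_valid])),
      redistribute = TRUE), error = function(e) NULL)
    if (is.null(pa_train) || is.null(pa_valid)) {
      warning("run_iterations: iteration ", it, " has too few eligible ",
              "pseudo-absence cells in a partition; skipped")
      skipped <- c(skipped, it)
      next
    }
    train_tab <- extract_env(bind_occurrences(presences[in_train, ], pa_train),
                             stack)
    ens <- fit_ensemble(train_tab, configs)
    valid_pts <- bind_occurrences(presences[in_valid, ], pa_valid)
    valid_tab <- extract_env(valid_pts, stack)
    scores <- predict_prob(ens, valid_tab)
    y <- train_labels(valid_tab)
    thr <- optimal_threshold(scores, y)
    cr <- confusion_rates(scores, y, thr)
    surf <- predict_surface(ens, stack)
    valid_region <- matrix(block_grid$values %in% iter$valid,
                           nrow(block_grid$values))
    boyce <- tryCatch(boyce_index(surf, valid_pts, region_mask = valid_region),
                      error = function(e) NA_real_)
    metrics[[length(metrics) + 1L]] <- metrics_report(
      auc = roc_auc(scores, y), tss = cr$sensitivity + cr$specificity - 1,
      sensitivity = cr$sensitivity, specificity = cr$specificity,
      precision = cr$precision, boyce = boyce, threshold = thr,
      n_presence = sum(y == 1L), n_absence = sum(y == 0L))
    thresholds <- c(thresholds, thr)
    surfaces[[length(surfaces) + 1L]] <- surf
    if (keep_ensembles) ensembles[[length(ensembles) + 1L]] <- ens
  }
  if (length(surfaces) == 0L)
    stop("run_iterations: no iteration completed")
  geom <- stack_geometry(stack)
  acc <- Reduce(`+`, lapply(surfaces, function(s) {
    v <- s$values; v[is.na(v)] <- 0; v
  }))
  n_ok <- Reduce(`+`, lapply(surfaces, function(s) !s$nodata_mask))
  mean_vals <- ifelse(n_ok > 0, acc / pmax(n_ok, 1L), NA_real_)
  surface <- raster_grid(mean_vals, geom$origin_lon, geom$origin_lat,
                         geom$cell_size, nodata_mask = n_ok == 0)
  structure(list(surface = surface, iteration_metrics = metrics,
                 thresholds = thresholds,
                 mean_threshold = mean(thresholds),
                 ensembles = ensembles, n_completed = length(metrics),
                 skipped = skipped),
            class = "iteration_result")
}
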