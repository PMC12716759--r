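#' Exact Shapley attribution for one feature vector
#'
#' Implements the Shapley value by full subset enumeration with an
#' interventional (marginal) value function: for a coalition S, the payoff
#' `v(S)` is the mean model output over the background rows with the features
#' in S replaced by the explained vector's values. The attribution of feature
#' i is the classical weighted sum of its marginal contributions
#' `sum over S of |S|!(|F|-|S|-1)!/|F|! * (v(S + i) - v(S))`. The base value
#' is `v(empty set)`, the expected model output over the background, and by
#' construction `base + sum(phi)` equals the model's prediction at `x`
#' (efficiency).
#'
#' @param predict_fun function mapping a feature data.frame/matrix to a
#'   numeric output vector (for example `function(d) predict_prob(member, d)`).
#' @param background data.frame or matrix of background rows (non-empty).
#' @param x a single feature vector (named numeric, or 1-row data.frame).
#' @param feature_names optional explicit feature order.
#' @return list with `phi` (named attribution vector), `base_value`,
#'   `prediction`.
#' @export
exact_shapley <- function(predict_fun, background, x, feature_names = NULL) {
  background <- as.matrix(as.data.frame(background))
  if (nrow(background) == 0L) stop("exact_shapley: background is empty")
  if (is.data.frame(x)) x <- unlist(x[1L, , drop = TRUE])
  if (is.null(feature_names))
    feature_names <- if (!is.null(names(x))) names(x) else colnames(background)
  p <- length(feature_names)
  if (p > 15L)
    stop("exact_shapley: ", p, " features exceeds the exact enumeration ",
         "bound of 15; a sampling approximation would be required")
  background <- background[, feature_names, drop = FALSE]
  x <- x[feature_names]
  v <- subset_values(predict_fun, background, x, feature_names)
  fact <- factorial(0:p)
  phi <- stats::setNames(numeric(p), feature_names)
  all_s <- 0:(2^p - 1L)
  sizes <- subset_sizes(p)
  for (i in seq_len(p)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- all_s[bitwAnd(all_s, bit) == 0L]
    s <- sizes[without + 1L]
    w <- fact[s + 1L] * fact[p - s] / fact[p + 1L]
    phi[i] <- sum(w * (v[without + bit + 1L] - v[without + 1L]))
  }
  list(phi = phi, base_value = v[1L], prediction = v[2^p])
}

subset_sizes <- function(p) {
  s <- 0:(2^p - 1L)
  vapply(s, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(p - 1L))) != 0L),
         numeric(1))
}

# evaluate v(S) for all 2^p subsets; batched so one predict call covers many
# subsets (cheap for tree ensembles)
subset_values <- function(predict_fun, background, x, feature_names,
                          max_rows = 262144L) {
  p <- length(feature_names); nbg <- nrow(background)
  n_subsets <- 2^p
  per_chunk <- max(1L, max_rows %/% nbg)
  v <- numeric(n_subsets)
  masks <- 0:(n_subsets - 1L)
  for (start in seq(1L, n_subsets, by = per_chunk)) {
    idx <- start:min(start + per_chunk - 1L, n_subsets)
    big <- background[rep(seq_len(nbg), times = length(idx)), , drop = FALSE]
    for (j in seq_along(idx)) {
      m <- masks[idx[j]]
      rows <- ((j - 1L) * nbg + 1L):(j * nbg)
      for (i in seq_len(p))
        if (bitwAnd(m, bitwShiftL(1L, i - 1L)) != 0L)
          big[rows, i] <- x[i]
    }
    preds <- predict_fun(as.data.frame(big))
    v[idx] <- colMeans(matrix(preds, nrow = nbg))
  }
  v
}

#' Shapley matrix for a set of samples
#'
#' Runs [exact_shapley] on every row of `samples` against one model,
#' assembling the per-sample, per-feature attribution matrix.
#'
#' @param object a fitted `niche_member` or `niche_ensemble`, or a plain
#'   prediction function.
#' @param background background sample (data.frame/matrix of feature rows).
#' @param samples data.frame of feature rows to explain.
#' @param feature_names optional explicit feature order.
#' @return object of class `shap_matrix`: `values` (samples x features),
#'   `base_value`, `predictions`, `feature_names`.
#' @export
shap_matrix <- function(object, background, samples, feature_names = NULL) {
  predict_fun <- if (is.function(object)) object
                 else function(d) predict_prob(object, d)
  if (is.null(feature_names))
    feature_names <- if (inherits(object, c("niche_member", "niche_ensemble")))
      object$feature_names else colnames(as.data.frame(background))
  samples <- as.data.frame(samples)[feature_names]
  res <- lapply(seq_len(nrow(samples)), function(r)
    exact_shapley(predict_fun, background, samples[r, , drop = FALSE],
                  feature_names))
  structure(list(
    values = do.call(rbind, lapply(res, function(z) z$phi)),
    base_value = res[[1L]]$base_value,
    predictions = vapply(res, function(z) z$prediction, numeric(1)),
    feature_names = feature_names),
    class = "shap_matrix")
}

#' Point-wise average of member Shapley matrices
#'
#' Averages the attribution matrices of the four ensemble members computed on
#' identical samples and features; the base value is the mean of the member
#' base values, so efficiency holds against the mean of the member
#' predictions.
#'
#' @param matrices list of `shap_matrix` objects with identical shapes,
#'   feature names and sample order.
#' @return a `shap_matrix`.
#' @export
ensemble_shap <- function(matrices) {
  if (length(matrices) == 0L) stop("ensemble_shap: empty matrix list")
  ref <- matrices[[1L]]
  for (m in matrices[-1L]) {
    if (!identical(dim(m$values), dim(ref$values)) ||
        !identical(m$feature_names, ref$feature_names))
      stop("ensemble_shap: matrices differ in shape or feature names")
  }
  structure(list(
    values = Reduce(`+`, lapply(matrices, `[[`, "values")) / length(matrices),
    base_value = mean(vapply(matrices, `[[`, numeric(1), "base_value")),
    predictions = rowMeans(vapply(matrices, `[[`,
                                  numeric(length(ref$predictions)),
                                  "predictions")),
    feature_names = ref$feature_names),
    class = "shap_matrix")
}

#' Global feature importance from a Shapley matrix
#'
#' Mean absolute attribution per feature, ranked descending; ties broken by
#' name.
#'
#' @param matrix a `shap_matrix` with at least one sample.
#' @return data.frame with columns `feature`, `mean_abs_shap`.
#' @export
global_importance <- function(matrix) {
  if (nrow(matrix$values) == 0L) stop("global_importance: empty matrix")
  s <- colMeans(abs(matrix$values))
  ord <- order(-s, matrix$feature_names)
  data.frame(feature = matrix$feature_names[ord], mean_abs_shap = unname(s[ord]),
             stringsAsFactors = FALSE)
}

#' Decision-path and dependence exports
#'
#' Tabular data behind the two standard attribution displays: the decision
#' export gives, per sample, the cumulative sum of attributions starting at
#' the base value with features ordered by ascending global importance (so
#' the final value equals the sample's prediction); the dependence export
#' pairs each feature's observed value with its attribution.
#'
#' @param matrix a `shap_matrix`.
#' @param samples the feature table the matrix was computed on.
#' @return list with data.frames `decision` (`sample`, `step`, `feature`,
#'   `phi`, `cumulative`) and `dependence` (`feature`, `value`, `phi`).
#' @export
export_decision_and_dependence <- function(matrix, samples) {
  samples <- as.data.frame(samples)[matrix$feature_names]
  if (nrow(samples) != nrow(matrix$values))
    stop("export_decision_and_dependence: samples misaligned with matrix")
  imp <- global_importance(matrix)
  ord <- rev(imp$feature)  # ascending importance
  n <- nrow(matrix$values); p <- length(ord)
  phi_ord <- matrix$values[, ord, drop = FALSE]
  cum <- matrix$base_value +
    t(apply(phi_ord, 1L, cumsum))
  if (n == 1L) cum <- matrix(cum, nrow = 1L)
  decision <- data.frame(
    sample = rep(seq_len(n), each = p),
    step = rep(seq_len(p), times = n),
    feature = rep(ord, times = n),
    phi = as.vector(t(phi_ord)),
    cumulative = as.vector(t(cum)),
    stringsAsFactors = FALSE)
  dependence <- data.frame(
    feature = rep(matrix$feature_names, each = n),
    value = unlist(samples, use.names = FALSE),
    phi = as.vector(matrix$values),
    stringsAsFactors = FALSE)
  list(decision = decision, dependence = dependence)
}
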