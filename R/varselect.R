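#' Collinearity filtering of predictor tables
#'
#' Greedy Pearson-correlation screening: among every pair of predictors with
#' `|r| >= threshold` (worst pair first), the lower-importance member is
#' dropped, until the surviving set is pairwise below the threshold. Ties in
#' importance are broken lexicographically by name (the alphabetically later
#' name is dropped). Constant columns have undefined correlations and are
#' dropped up front with a warning.
#'
#' @param samples data.frame of numeric predictor columns (a `label` column,
#'   if present, is ignored).
#' @param threshold absolute Pearson correlation above which a pair is
#'   considered collinear (default 0.8).
#' @param importance optional named numeric scores (higher = keep); defaults
#'   to equal importance.
#' @return object of class `selection_report`: list with `kept` (names),
#'   `dropped` (data.frame `name`, `partner`, `r`), `importance`.
#' @export
correlation_filter <- function(samples, threshold = 0.8, importance = NULL) {
  samples <- samples[, setdiff(names(samples), "label"), drop = FALSE]
  if (nrow(samples) < 2L) stop("correlation_filter: need at least 2 rows")
  if (!all(vapply(samples, is.numeric, logical(1))))
    stop("correlation_filter: all predictor columns must be numeric")
  nm <- names(samples)
  if (is.null(importance)) importance <- stats::setNames(rep(1, length(nm)), nm)
  if (!all(nm %in% names(importance)))
    stop("correlation_filter: importance must cover all columns")
  dropped <- data.frame(name = character(), partner = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  const <- nm[vapply(samples, function(x) stats::sd(x) == 0, logical(1))]
  if (length(const)) {
    warning("correlation_filter: dropping constant column(s): ",
            paste(const, collapse = ", "))
    dropped <- rbind(dropped, data.frame(name = const, partner = NA_character_,
                                         r = NA_real_))
  }
  kept <- setdiff(nm, const)
  cm <- if (length(kept) >= 2L) abs(stats::cor(samples[kept])) else NULL
  while (length(kept) >= 2L) {
    diag(cm) <- 0
    worst <- max(cm)
    if (worst < threshold) break
    idx <- which(cm == worst, arr.ind = TRUE)[1L, ]
    a <- kept[idx[1L]]; b <- kept[idx[2L]]
    drop <- if (importance[a] < importance[b]) a
            else if (importance[b] < importance[a]) b
            else max(a, b)  # lexicographic tie-break: later name goes
    partner <- if (drop == a) b else a
    dropped <- rbind(dropped, data.frame(name = drop, partner = partner,
                                         r = worst))
    kept <- setdiff(kept, drop)
    cm <- cm[kept, kept, drop = FALSE]
  }
  structure(list(kept = kept, dropped = dropped,
                 importance = importance[nm[nm %in% names(importance)]],
                 threshold = threshold),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> kept %d, dropped %d (|r| >= %.2f)\n",
              length(x$kept), nrow(x$dropped), x$threshold))
  invisible(x)
}

#' Ensemble variable importance
#'
#' Mean impurity-based importance across the members of a fitted four-member
#' ensemble (Gini-style impurity decrease for random forests, gain for
#' gradient boosted trees), each member normalized to sum to one before
#' averaging; the result is renormalized to sum to one.
#'
#' @param ensemble a fitted `niche_ensemble` (see [fit_ensemble]) or a single
#'   `niche_member`.
#' @return named numeric vector of scores summing to 1, in feature order.
#' @export
model_importance <- function(ensemble) {
  members <- if (inherits(ensemble, "niche_member")) list(ensemble)
             else if (inherits(ensemble, "niche_ensemble")) ensemble$members
             else stop("model_importance: need a fitted member or ensemble")
  per <- lapply(members, member_importance)
  feats <- members[[1L]]$feature_names
  m <- vapply(per, function(p) {
    v <- stats::setNames(rep(0, length(feats)), feats)
    v[names(p)] <- p
    if (sum(v) > 0) v / sum(v) else v
  }, numeric(length(feats)))
  m <- matrix(m, nrow = length(feats), dimnames = list(feats, NULL))
  score <- rowMeans(m)
  score / sum(score)
}

member_importance <- function(member) {
  if (member$algorithm == "random_forest") {
    member$model$variable.importance
  } else {
    imp <- xgboost::xgb.importance(model = member$model)
    stats::setNames(imp$Gain, imp$Feature)
  }
}
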