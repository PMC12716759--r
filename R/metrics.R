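#' Confusion-matrix rates at a threshold
#'
#' Scores at or above the threshold are predicted positive (presence).
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical) observed labels, 1 = presence.
#' @param threshold decision threshold.
#' @return list with `sensitivity` = TP/(TP+FN), `specificity` = TN/(TN+FP),
#'   `precision` = TP/(TP+FP) (`NA` when no positives are predicted).
#' @export
confusion_rates <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("confusion_rates: both classes must be present")
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L); fn <- sum(!pred & labels == 1L)
  tn <- sum(!pred & labels == 0L); fp <- sum(pred & labels == 0L)
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp))
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random presence outscores
#' a random absence, ties counted half; computed from midranks.
#'
#' @inheritParams confusion_rates
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("roc_auc: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold maximizing sensitivity + specificity
#'
#' Searches the observed scores (the maximum-training-sensitivity-plus-
#' specificity rule); among tied optima the lowest threshold is returned.
#'
#' @inheritParams confusion_rates
#' @export
optimal_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("optimal_threshold: both classes must be present")
  cand <- sort(unique(scores))
  ss <- vapply(cand, function(t) {
    cr <- confusion_rates(scores, labels, t)
    cr$sensitivity + cr$specificity
  }, numeric(1))
  cand[which(ss >= max(ss) - 1e-12)[1L]]
}

#' Continuous Boyce index
#'
#' Presence-only calibration measure: suitability is first mapped through its
#' own landscape-wide cumulative distribution, and the resulting `[0, 1]`
#' quantile axis is covered by `n_bins` overlapping moving windows of width
#' `window_width`. In each window the predicted-to-expected ratio P/E is the
#' fraction of presences falling there divided by the fraction of valid
#' landscape cells there. The index is the Spearman rank correlation of P/E
#' against the window midpoints; windows with E = 0 are dropped. Working on
#' the quantile axis makes the index exactly invariant under rank-preserving
#' transforms of the surface and keeps the expected mass per window nearly
#' equal, avoiding the empty high-suitability windows of value-axis
#' binning on skewed surfaces. Returns `NA` when the correlation is
#' undefined (for example, all presences in one window).
#'
#' @param surface a `raster_grid` suitability surface in `[0, 1]`.
#' @param presences an [occurrence_set] (presence rows are used).
#' @param n_bins number of moving windows (default 10).
#' @param window_width window width on the quantile axis (default 0.2).
#' @param region_mask optional logical matrix restricting the expected
#'   (landscape) distribution to the region the presences were observed in —
#'   for example the validation blocks of a cross-validation split, so that
#'   P and E describe the same domain.
#' @export
boyce_index <- function(surface, presences, n_bins = 10, window_width = 0.2,
                        region_mask = NULL) {
  pres <- presences[presences$label == "presence", , drop = FALSE]
  ci <- cell_index(surface, pres$lon, pres$lat)
  hsi_p <- surface$values[cbind(ci$row, ci$col)]
  hsi_p <- hsi_p[!is.na(hsi_p)]
  if (length(hsi_p) < 2L) stop("boyce_index: too few presences on valid cells")
  sel <- !surface$nodata_mask
  if (!is.null(region_mask)) sel <- sel & as.matrix(region_mask)
  hsi_all <- surface$values[sel]
  F <- stats::ecdf(hsi_all)
  hsi_p <- F(hsi_p); hsi_all <- F(hsi_all)
  starts <- seq(0, 1 - window_width, length.out = n_bins)
  mid <- starts + window_width / 2
  pe <- vapply(starts, function(s) {
    inw <- function(v) v >= s & v <= s + window_width
    E <- mean(inw(hsi_all))
    if (E == 0) return(NA_real_)
    mean(inw(hsi_p)) / E
  }, numeric(1))
  ok <- !is.na(pe)
  if (sum(ok) < 2L) return(NA_real_)
  suppressWarnings(stats::cor(pe[ok], mid[ok], method = "spearman"))
}

#' Bundle evaluation metrics for one model iteration
#'
#' Validates the defining identity TSS = sensitivity + specificity - 1 and
#' the admissible ranges of each metric.
#'
#' @param auc,sensitivity,specificity,precision rates in `[0, 1]`.
#' @param tss true skill statistic in `[-1, 1]`.
#' @param boyce Boyce index in `[-1, 1]` (may be `NA`).
#' @param threshold decision threshold in `(0, 1)`.
#' @param n_presence,n_absence evaluation sample sizes.
#' @return list of class `metrics_report`.
#' @export
metrics_report <- function(auc, tss, sensitivity, specificity, precision,
                           boyce, threshold, n_presence, n_absence) {
  if (abs(tss - (sensitivity + specificity - 1)) > 1e-12)
    stop("metrics_report: TSS must equal sensitivity + specificity - 1")
  rates <- c(auc = auc, sensitivity = sensitivity, specificity = specificity)
  if (any(rates < -1e-12 | rates > 1 + 1e-12))
    stop("metrics_report: rates must lie in [0, 1]")
  if (!is.na(boyce) && (boyce < -1 - 1e-12 || boyce > 1 + 1e-12))
    stop("metrics_report: boyce must lie in [-1, 1]")
  structure(list(auc = auc, tss = tss, sensitivity = sensitivity,
                 specificity = specificity, precision = precision,
                 boyce = boyce, threshold = threshold,
                 n_presence = n_presence, n_absence = n_absence),
            class = "metrics_report")
}

#' Summarize per-iteration metrics as mean and sd
#' @param reports list of [metrics_report] objects.
#' @return data.frame with one row per iteration plus `mean` and `sd` rows.
#' @export
summarize_metrics <- function(reports) {
  cols <- c("auc", "tss", "sensitivity", "specificity", "precision",
            "boyce", "threshold")
  tab <- as.data.frame(t(vapply(reports, function(r)
    unlist(r[cols]), numeric(length(cols)))))
  names(tab) <- cols
  tab$iteration <- as.character(seq_len(nrow(tab)))
  mm <- colMeans(tab[cols], na.rm = TRUE)
  ss <- vapply(tab[cols], stats::sd, numeric(1), na.rm = TRUE)
  rbind(tab,
        data.frame(as.list(mm), iteration = "mean"),
        data.frame(as.list(ss), iteration = "sd"))
}
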