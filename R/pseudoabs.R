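#' Eligibility mask for pseudo-absence sampling
#'
#' A boolean grid marking the cells from which pseudo-absences may be drawn,
#' together with the provenance of the rule that produced it. Eligible cells
#' are always valid (non-nodata) and never presence-occupied.
#'
#' @param mask logical matrix, `TRUE` = eligible.
#' @param geom grid geometry (a `raster_grid` or geometry list).
#' @param provenance named list of the parameters used.
#' @return object of class `eligibility_mask`.
#' @export
eligibility_mask <- function(mask, geom, provenance = list()) {
  if (inherits(geom, "raster_grid")) geom <- grid_geometry(geom)
  mask <- as.matrix(mask); mode(mask) <- "logical"
  if (nrow(mask) != geom$n_rows || ncol(mask) != geom$n_cols)
    stop("eligibility_mask: mask shape must match the grid")
  structure(list(mask = mask, geom = geom, provenance = provenance),
            class = "eligibility_mask")
}

#' @export
print.eligibility_mask <- function(x, ...) {
  cat(sprintf("<eligibility_mask> %d eligible of %d cells (%s)\n",
              sum(x$mask), length(x$mask),
              paste(names(x$provenance), collapse = ", ")))
  invisible(x)
}

#' Export an eligibility mask as a 0/1 raster
#' @param x an [eligibility_mask].
#' @export
mask_as_raster <- function(x) {
  raster_grid(matrix(as.integer(x$mask), x$geom$n_rows, x$geom$n_cols),
              x$geom$origin_lon, x$geom$origin_lat, x$geom$cell_size,
              is_categorical = TRUE)
}

continuous_layers <- function(stack) {
  stack$layers[!vapply(stack$layers, function(l) l$is_categorical, logical(1))]
}

presence_cell_matrix <- function(stack, presences) {
  pres <- presences[presences$label == "presence", , drop = FALSE]
  ci <- cell_index(stack_geometry(stack), pres$lon, pres$lat)
  cbind(ci$row, ci$col)
}

#' Environmental-profiling eligibility filter
#'
#' First arm of the dual pseudo-absence filter. Per continuous layer, the
#' presence values define an envelope between the configured quantiles; a
#' cell that sits inside the envelope on every layer is environmentally
#' similar to the presences and therefore INELIGIBLE. Cells outside the
#' envelope on at least one layer are eligible. Presence-occupied and nodata
#' cells are never eligible.
#'
#' @param stack an [env_stack].
#' @param presences presence [occurrence_set] (at least 5 presences).
#' @param envelope_quantiles lower/upper envelope quantiles (default 5%/95%).
#' @return an [eligibility_mask].
#' @export
environmental_profile_mask <- function(stack, presences,
                                       envelope_quantiles = c(0.05, 0.95)) {
  cont <- continuous_layers(stack)
  if (length(cont) == 0L)
    stop("environmental_profile_mask: no continuous layers")
  if (sum(presences$label == "presence") < 5L)
    stop("environmental_profile_mask: need at least 5 presences")
  pidx <- presence_cell_matrix(stack, presences)
  valid <- stack_valid_mask(stack)
  inside_all <- valid
  for (l in cont) {
    pv <- l$values[pidx]
    q <- stats::quantile(pv, envelope_quantiles, na.rm = TRUE, names = FALSE)
    inside_all <- inside_all & l$values >= q[1L] & l$values <= q[2L]
  }
  inside_all[is.na(inside_all)] <- FALSE
  elig <- valid & !inside_all
  elig[pidx] <- FALSE
  if (!any(elig))
    stop("environmental_profile_mask: no eligible cells; the landscape may be",
         " too environmentally uniform around the presences")
  eligibility_mask(elig, stack_geometry(stack),
                   provenance = list(filter = "environmental_profile",
                                     envelope_quantiles = envelope_quantiles))
}

#' K-means eligibility filter
#'
#' Second arm of the dual filter. All valid cells are clustered in
#' standardized continuous environmental space; within a run, each cluster's
#' presence density (presences per member cell) is computed, and clusters in
#' the lowest `presence_poor_quantile` of density are flagged as presence-
#' poor. Flags are accumulated over `runs` seeded random initializations and
#' a cell becomes eligible when flagged in more than half of the runs
#' (majority vote), making the result stable against the initialization
#' sensitivity of K-means.
#'
#' @inheritParams environmental_profile_mask
#' @param k number of clusters (>= 2).
#' @param runs number of seeded K-means restarts (>= 1).
#' @param presence_poor_quantile density quantile below which a cluster is
#'   flagged (default: lowest quartile).
#' @param seed integer seed; run `r` uses `seed + r`.
#' @return an [eligibility_mask].
#' @export
kmeans_eligibility <- function(stack, presences, k = 8, runs = 5,
                               presence_poor_quantile = 0.25, seed = 1) {
  if (k < 2L) stop("kmeans_eligibility: k must be >= 2")
  if (runs < 1L) stop("kmeans_eligibility: runs must be >= 1")
  cont <- continuous_layers(stack)
  if (length(cont) == 0L) stop("kmeans_eligibility: no continuous layers")
  valid <- stack_valid_mask(stack)
  vidx <- which(valid)
  if (k > length(vidx)) stop("kmeans_eligibility: k exceeds valid-cell count")
  X <- vapply(cont, function(l) {
    v <- l$values[vidx]
    s <- stats::sd(v)
    if (s == 0) stop("kmeans_eligibility: constant layer; environment degenerate")
    (v - mean(v)) / s
  }, numeric(length(vidx)))
  pidx <- presence_cell_matrix(stack, presences)
  nr <- stack_geometry(stack)$n_rows
  plin <- (pidx[, 2L] - 1L) * nr + pidx[, 1L]
  prow <- match(plin, vidx)  # presences may repeat cells; keep multiplicity
  prow <- prow[!is.na(prow)]
  votes <- integer(length(vidx))
  for (r in seq_len(runs)) {
    set.seed(as.integer(seed) + r)
    km <- stats::kmeans(X, centers = k, nstart = 1, iter.max = 100)
    dens <- tabulate(km$cluster[prow], nbins = k) / km$size
    flagged <- dens <= stats::quantile(dens, presence_poor_quantile,
                                       names = FALSE)
    votes <- votes + as.integer(flagged[km$cluster])
  }
  elig <- matrix(FALSE, stack_geometry(stack)$n_rows,
                 stack_geometry(stack)$n_cols)
  elig[vidx[votes > runs / 2]] <- TRUE
  elig[pidx] <- FALSE
  eligibility_mask(elig, stack_geometry(stack),
                   provenance = list(filter = "kmeans", k = k, runs = runs,
                                     presence_poor_quantile = presence_poor_quantile,
                                     seed = seed, rule = "majority_vote"))
}

intersect_masks <- function(masks) {
  if (inherits(masks, "eligibility_mask")) masks <- list(masks)
  m <- masks[[1L]]$mask
  for (em in masks[-1L]) {
    if (!identical(dim(em$mask), dim(m)))
      stop("sample_pseudo_absences: masks on different geometries")
    m <- m & em$mask
  }
  list(mask = m, geom = masks[[1L]]$geom)
}

#' Sample balanced pseudo-absence points
#'
#' Draws cells uniformly without replacement from the intersection of the
#' supplied eligibility masks, either a flat total `n` or per spatial block.
#' In per-block mode the target counts (normally the per-block presence
#' counts of one cross-validation partition) are matched exactly; with
#' `redistribute = TRUE` a block whose eligible cells cannot cover its target
#' contributes what it has and the shortfall is drawn from the remaining
#' eligible cells of the other listed blocks, preserving the partition-level
#' balance. Sampled points are jittered uniformly within their cell.
#'
#' @param masks an [eligibility_mask] or list of masks (intersected).
#' @param n total number of points (flat mode).
#' @param seed integer seed.
#' @param block_assignment optional list with `block_grid` (integer
#'   `raster_grid` of block ids) and `counts` (named table/vector,
#'   block id -> target count).
#' @param redistribute logical; see above (default `FALSE`: shortfall is an
#'   error).
#' @param species_id attached to the returned records.
#' @return an [occurrence_set] with label `"pseudo_absence"`. In per-block
#'   mode the block id of each point is attached as attribute `"block"`.
#' @export
sample_pseudo_absences <- function(masks, n = NULL, seed = 1,
                                   block_assignment = NULL,
                                   redistribute = FALSE,
                                   species_id = "pseudo") {
  im <- intersect_masks(masks)
  elig <- which(im$mask)
  if (length(elig) == 0L)
    stop("sample_pseudo_absences: empty eligibility intersection")
  set.seed(as.integer(seed))
  if (is.null(block_assignment)) {
    if (is.null(n) || n < 1L) stop("sample_pseudo_absences: n must be >= 1")
    if (length(elig) < n)
      stop("sample_pseudo_absences: only ", length(elig),
           " eligible cells for n = ", n)
    chosen <- if (length(elig) == n) elig
              else elig[sample.int(length(elig), n)]
    blocks <- NULL
  } else {
    bg <- block_assignment$block_grid
    counts <- block_assignment$counts
    ids <- as.integer(names(counts))
    want <- as.integer(counts)
    bvals <- bg$values[elig]
    chosen <- integer(0); blocks <- integer(0); short <- 0L
    pool_used <- logical(length(elig))
    for (j in seq_along(ids)) {
      avail <- which(bvals == ids[j] & !pool_used)
      take <- min(length(avail), want[j])
      if (take < want[j] && !redistribute)
        stop("sample_pseudo_absences: block ", ids[j], " has only ",
             length(avail), " eligible cells for ", want[j], " points")
      sel <- if (take == 0L) integer(0)
             else if (length(avail) == take) avail
             else avail[sample.int(length(avail), take)]
      pool_used[sel] <- TRUE
      chosen <- c(chosen, elig[sel]); blocks <- c(blocks, rep(ids[j], take))
      short <- short + (want[j] - take)
    }
    if (short > 0L) {
      pool <- which(bvals %in% ids & !pool_used)
      if (length(pool) < short)
        stop("sample_pseudo_absences: partition has only ",
             length(chosen) + length(pool), " eligible cells for ",
             sum(want), " points")
      sel <- if (length(pool) == short) pool
             else pool[sample.int(length(pool), short)]
      chosen <- c(chosen, elig[sel]); blocks <- c(blocks, bvals[sel])
    }
  }
  nr <- im$geom$n_rows; cs <- im$geom$cell_size
  row <- (chosen - 1L) %% nr + 1L
  col <- (chosen - 1L) %/% nr + 1L
  lon <- im$geom$origin_lon + (col - 1L) * cs +
    stats::runif(length(chosen), 1e-6, 1 - 1e-6) * cs
  lat <- im$geom$origin_lat - (row - 1L) * cs -
    stats::runif(length(chosen), 1e-6, 1 - 1e-6) * cs
  out <- occurrence_set(lon, lat, "pseudo_absence", species_id)
  if (!is.null(blocks)) attr(out, "block") <- blocks
  out
}
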