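#' Synthetic landscape configuration
#'
#' Parameters of the synthetic arid-landscape generator that stands in for
#' real climate/soil raster downloads: spatially autocorrelated continuous
#' climate fields, a clumped categorical soil-class field, a continuous soil
#' available-water-capacity (AWC) field, and known truth suitability surfaces
#' for a host shrub and a host-dependent parasite.
#'
#' The truth model composes a logistic climate response
#' `logit(p_clim) = sum(effects * climate layers)` with a soil response
#' `p_soil = class_suitability[code] * exp(-(AWC - opt)^2 / (2 width^2))`,
#' and takes per-cell minima: the host's final truth is
#' `min(p_clim_host, p_soil_host)` and the parasite's is
#' `min(p_clim_parasite, p_soil_parasite, host final)` — the "barrel effect"
#' composition in which the least favourable factor rules.
#'
#' @param n_rows,n_cols grid size in cells.
#' @param autocorr_length Gaussian-field correlation scale, in cells.
#' @param n_climate number of continuous climate-like layers.
#' @param n_soil_classes number of integer soil-class codes.
#' @param climate_effects host per-layer coefficients of the truth logit.
#' @param parasite_climate_effects parasite coefficients; default is a shifted
#'   version of the host's so the two climate niches overlap strongly but are
#'   not identical.
#' @param soil_class_suitability host per-code suitability in `[0, 1]`.
#' @param parasite_soil_class_suitability parasite per-code suitability.
#' @param awc_optimum,awc_width centre and width of the unimodal AWC response.
#' @param origin_lon,origin_lat,cell_size georeference of the generated grids.
#' @param seed integer seed; identical configs give bit-identical landscapes.
#' @return list of class `landscape_config`.
#' @export
landscape_config <- function(n_rows = 100, n_cols = 100, autocorr_length = 6,
                             n_climate = 5, n_soil_classes = 6,
                             climate_effects = c(1.8, -1.2, 0.9, 0.5, 0),
                             parasite_climate_effects = NULL,
                             soil_class_suitability = c(0.95, 0.85, 0.65, 0.45, 0.3, 0.15),
                             parasite_soil_class_suitability = c(0.9, 0.9, 0.55, 0.5, 0.2, 0.1),
                             awc_optimum = 0.55, awc_width = 0.3,
                             origin_lon = 75, origin_lat = 48, cell_size = 0.05,
                             seed = 1) {
  if (n_rows <= 0 || n_cols <= 0 || n_climate <= 0 || n_soil_classes <= 0)
    stop("landscape_config: all counts must be positive")
  if (length(climate_effects) != n_climate)
    stop("landscape_config: climate_effects must have length n_climate")
  if (is.null(parasite_climate_effects))
    parasite_climate_effects <- 0.7 * climate_effects +
      rep_len(c(0.5, 0.1, -0.3, 0.2, 0.4), n_climate)
  if (length(parasite_climate_effects) != n_climate)
    stop("landscape_config: parasite_climate_effects must have length n_climate")
  soil_class_suitability <- rep_len(soil_class_suitability, n_soil_classes)
  parasite_soil_class_suitability <- rep_len(parasite_soil_class_suitability,
                                             n_soil_classes)
  if (any(soil_class_suitability < 0 | soil_class_suitability > 1) ||
      any(parasite_soil_class_suitability < 0 | parasite_soil_class_suitability > 1))
    stop("landscape_config: soil class suitabilities must lie in [0, 1]")
  if (awc_width <= 0) stop("landscape_config: awc_width must be positive")
  structure(as.list(environment()), class = "landscape_config")
}

# separable Gaussian smoothing with edge renormalization via row-stochastic
# band matrices; sigma in cells
gaussian_smooth <- function(mat, sigma) {
  band <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-d^2 / (2 * sigma^2))
    k[d > ceiling(3 * sigma)] <- 0
    k / rowSums(k)
  }
  band(nrow(mat)) %*% mat %*% t(band(ncol(mat)))
}

standardize_grid <- function(vals) {
  (vals - mean(vals)) / stats::sd(as.vector(vals))
}

#' Generate a synthetic landscape with known truth suitability
#'
#' Climate layers are seeded white noise smoothed at the configured
#' correlation scale and standardized to mean 0, sd 1. The soil class layer
#' is a Voronoi tessellation of seeded points (clumped, contiguous units);
#' AWC is a smoothed field mapped through the normal CDF into `[0, 1]`.
#' Truth surfaces follow the composition documented in [landscape_config].
#'
#' @param config a [landscape_config].
#' @return list with elements `stack` (an [env_stack] of layers
#'   `clim1..climK`, `soil_class`, `awc`) and `truth` (surfaces
#'   `climate_truth_host`, `soil_truth_host`, `climate_truth_parasite`,
#'   `soil_truth_parasite`, `host_final_truth`, `parasite_final_truth`).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(as.integer(config$seed))
  nr <- config$n_rows; nc <- config$n_cols
  mk <- function(vals, categorical = FALSE)
    raster_grid(vals, config$origin_lon, config$origin_lat, config$cell_size,
                is_categorical = categorical)
  clim <- vector("list", config$n_climate)
  for (i in seq_len(config$n_climate)) {
    z <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                         config$autocorr_length)
    clim[[i]] <- mk(standardize_grid(z))
  }
  names(clim) <- paste0("clim", seq_len(config$n_climate))
  # clumped soil units: Voronoi cells of seeded points
  ns <- config$n_soil_classes
  sr <- stats::runif(ns, 0.5, nr + 0.5); sc <- stats::runif(ns, 0.5, nc + 0.5)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d2 <- vapply(seq_len(ns),
               function(k) as.vector((rows - sr[k])^2 + (cols - sc[k])^2),
               numeric(nr * nc))
  soil_code <- matrix(max.col(-d2, ties.method = "first"), nr, nc)
  awc_z <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                           config$autocorr_length)
  awc <- stats::pnorm(standardize_grid(awc_z))
  stack <- env_stack(c(clim, list(soil_class = mk(soil_code, categorical = TRUE),
                                  awc = mk(awc))))
  climate_truth <- function(effects) {
    logit <- Reduce(`+`, Map(function(l, b) b * l$values, clim, as.list(effects)))
    mk(stats::plogis(logit))
  }
  soil_truth <- function(class_suit) {
    mk(class_suit[soil_code] *
         exp(-(awc - config$awc_optimum)^2 / (2 * config$awc_width^2)))
  }
  ct_h <- climate_truth(config$climate_effects)
  st_h <- soil_truth(config$soil_class_suitability)
  ct_p <- climate_truth(config$parasite_climate_effects)
  st_p <- soil_truth(config$parasite_soil_class_suitability)
  host_final <- mk(pmin(ct_h$values, st_h$values))
  parasite_final <- mk(pmin(ct_p$values, st_p$values, host_final$values))
  list(stack = stack,
       truth = list(climate_truth_host = ct_h, soil_truth_host = st_h,
                    climate_truth_parasite = ct_p, soil_truth_parasite = st_p,
                    host_final_truth = host_final,
                    parasite_final_truth = parasite_final),
       config = config)
}

#' Sample presence points from a truth suitability surface
#'
#' Draws cells with probability proportional to the truth habitat-suitability
#' index (equivalently: uniform cell proposals accepted with probability equal
#' to the cell's HSI, repeated until `n_target` acceptances), then jitters
#' each point uniformly within its cell.
#'
#' @param truth a `raster_grid` suitability surface with values in `[0, 1]`.
#' @param n_target number of presence points to draw (0 gives an empty set).
#' @param seed integer seed.
#' @param species_id species identifier attached to the records.
#' @return an [occurrence_set] of presences.
#' @export
sample_occurrences <- function(truth, n_target, seed, species_id = "species") {
  stopifnot(inherits(truth, "raster_grid"), n_target >= 0)
  if (n_target == 0L) return(occurrence_set())
  ok <- which(!truth$nodata_mask)
  w <- truth$values[ok]
  if (sum(w) <= 0)
    stop("sample_occurrences: truth surface is identically zero; sampling impossible")
  set.seed(as.integer(seed))
  pick <- ok[sample.int(length(ok), n_target, replace = TRUE, prob = w)]
  nr <- nrow(truth$values)
  row <- (pick - 1L) %% nr + 1L
  col <- (pick - 1L) %/% nr + 1L
  cs <- truth$cell_size
  lon <- truth$origin_lon + (col - 1L) * cs + stats::runif(n_target, 1e-6, 1 - 1e-6) * cs
  lat <- truth$origin_lat - (row - 1L) * cs - stats::runif(n_target, 1e-6, 1 - 1e-6) * cs
  occurrence_set(lon, lat, "presence", species_id)
}
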