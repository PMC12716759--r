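#' Climate-change scenario definition
#'
#' A named scenario applies additive shifts to (standardized) climate layers;
#' soil layers are treated as temporally static and never shifted. The
#' reference scenario must be named `"current"` and carry zero shifts.
#'
#' @param name scenario label (for example `"current"`, `"ssp126"`).
#' @param climate_shift named numeric vector of per-layer additive deltas.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(name, climate_shift = numeric()) {
  if (name == "current" && length(climate_shift) && any(climate_shift != 0))
    stop("scenario_config: the 'current' scenario must have zero shifts")
  structure(list(name = name, climate_shift = climate_shift,
                 soil_static = TRUE),
            class = "scenario_config")
}

#' Default scenario set for a synthetic landscape
#'
#' Builds `current` plus three increasingly adverse scenarios by shifting
#' each climate layer against the sign of its truth coefficient, with
#' severities mirroring a low/medium/high emission ladder.
#'
#' @param climate_effects named or unnamed coefficients per climate layer
#'   (layer `i` is `clim<i>` when unnamed).
#' @param severities named severities in standardized units.
#' @return named list of [scenario_config]s.
#' @export
default_scenarios <- function(climate_effects,
                              severities = c(ssp126 = 0.5, ssp245 = 0.8,
                                             ssp585 = 1.2)) {
  nm <- names(climate_effects)
  if (is.null(nm)) nm <- paste0("clim", seq_along(climate_effects))
  out <- list(current = scenario_config("current",
                                        stats::setNames(rep(0, length(nm)), nm)))
  for (s in names(severities)) {
    shift <- -sign(climate_effects) * severities[[s]]
    out[[s]] <- scenario_config(s, stats::setNames(as.numeric(shift), nm))
  }
  out
}

#' Apply a scenario's climate shifts to a stack
#'
#' @param stack an [env_stack].
#' @param scenario a [scenario_config].
#' @return shifted [env_stack] (soil and unnamed layers untouched).
#' @export
apply_scenario <- function(stack, scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  layers <- stack$layers
  for (nm in names(scenario$climate_shift)) {
    if (!nm %in% names(layers)) next
    l <- layers[[nm]]
    layers[[nm]] <- raster_grid(l$values + scenario$climate_shift[[nm]],
                                l$origin_lon, l$origin_lat, l$cell_size,
                                nodata_mask = l$nodata_mask,
                                is_categorical = l$is_categorical)
  }
  env_stack(layers)
}

#' Nested default region masks
#'
#' Three nested rectangular regions (whole landscape, a central window, and
#' an inner core) used for regional suitable-area accounting on synthetic
#' landscapes.
#'
#' @param geom a `raster_grid` or geometry list.
#' @return named list of logical matrices.
#' @export
default_region_masks <- function(geom) {
  if (inherits(geom, "raster_grid")) geom <- grid_geometry(geom)
  nr <- geom$n_rows; nc <- geom$n_cols
  box <- function(frac) {
    m <- matrix(FALSE, nr, nc)
    r <- max(1L, round(nr * (1 - frac) / 2)):min(nr, round(nr * (1 + frac) / 2))
    c <- max(1L, round(nc * (1 - frac) / 2)):min(nc, round(nc * (1 + frac) / 2))
    m[r, c] <- TRUE
    m
  }
  list(world = matrix(TRUE, nr, nc), central = box(0.6), core = box(0.3))
}

project_surface <- function(ensembles, stack) {
  surfaces <- lapply(ensembles, predict_surface, stack = stack)
  if (length(surfaces) == 1L) return(surfaces[[1L]])
  ref <- surfaces[[1L]]
  vals <- Reduce(`+`, lapply(surfaces, `[[`, "values")) / length(surfaces)
  raster_grid(vals, ref$origin_lon, ref$origin_lat, ref$cell_size,
              nodata_mask = ref$nodata_mask)
}

#' Run the full single-species modelling workflow
#'
#' Thin -> collinearity screening (climate predictors) -> eligibility masks
#' (environmental profile + K-means majority vote) -> repeated spatially
#' blocked iterations for the climate model and, independently, the soil
#' model -> mean surfaces and mean optimal thresholds -> minimum-rule dual
#' surface and dual-threshold binary maps.
#'
#' @param stack an [env_stack] holding climate and soil layers.
#' @param presences presence [occurrence_set].
#' @param climate_layers,soil_layers layer names of the two predictor sets.
#' @param n_iterations repeated block splits (default 10).
#' @param block_size block edge in cells (default: short grid side / 5).
#' @param seed master seed; all stage seeds derive from it.
#' @param k,runs,presence_poor_quantile K-means filter settings.
#' @param envelope_quantiles environmental-profile envelope.
#' @param correlation_threshold collinearity cutoff (default 0.8).
#' @param species_id label carried through the artifacts.
#' @return list of class `species_result`: thinned presences, selection
#'   report, per-model [run_iterations] results (`climate`, `soil`), mean
#'   surfaces (`climate_surface`, `soil_surface`, `dual_surface`), mean
#'   thresholds, binary maps (`climate_binary`, `soil_binary`,
#'   `dual_binary`), cv plan and masks.
#' @export
run_species <- function(stack, presences, climate_layers, soil_layers,
                        n_iterations = 10, block_size = NULL, seed = 1,
                        k = 8, runs = 5, presence_poor_quantile = 0.25,
                        envelope_quantiles = c(0.05, 0.95),
                        correlation_threshold = 0.8,
                        species_id = unique(presences$species_id)[1L]) {
  seed <- as.integer(seed)
  geom <- stack_geometry(stack)
  pres <- thin_occurrences(presences, geom, seed = seed)
  pres <- pres[pres$label == "presence", , drop = FALSE]
  clim_stack <- stack_subset(stack, climate_layers)
  soil_stack <- stack_subset(stack, soil_layers)

  # collinearity screening with importance from a preliminary forest
  prof0 <- environmental_profile_mask(clim_stack, pres, envelope_quantiles)
  pa0 <- sample_pseudo_absences(prof0, n = nrow(pres), seed = seed + 777)
  tab0 <- extract_env(bind_occurrences(pres, pa0), clim_stack)
  prelim <- fit_member(model_config("random_forest", "interm", seed = seed + 5),
                       tab0)
  selection <- correlation_filter(tab0, threshold = correlation_threshold,
                                  importance = model_importance(prelim))
  clim_stack <- stack_subset(clim_stack, selection$kept)

  if (is.null(block_size))
    block_size <- max(1L, floor(min(geom$n_rows, geom$n_cols) / 5))
  block_grid <- make_blocks(geom, block_size)
  plan <- split_blocks(block_grid, n_iterations = n_iterations, seed = seed)

  # each sub-model applies the same training protocol in its own predictor
  # space: dual-filtered eligibility (environmental profiling + K-means
  # majority vote) over that sub-model's layers
  run_model <- function(sub_stack, sub_seed) {
    masks <- list(
      environmental_profile_mask(sub_stack, pres, envelope_quantiles),
      kmeans_eligibility(sub_stack, pres, k = k, runs = runs,
                         presence_poor_quantile = presence_poor_quantile,
                         seed = sub_seed + 300L))
    list(result = run_iterations(sub_stack, pres, plan, masks,
                                 configs = default_ensemble_configs(sub_seed),
                                 seed = sub_seed),
         masks = masks)
  }
  clim <- run_model(clim_stack, seed + 100L)
  soil <- run_model(soil_stack, seed + 200L)

  dual_surface <- min_overlay(list(clim$result$surface, soil$result$surface))
  climate_binary <- binarize(clim$result$surface, clim$result$mean_threshold)
  soil_binary <- binarize(soil$result$surface, soil$result$mean_threshold)
  dual_binary <- co_suitable_map(list(climate_binary, soil_binary))

  structure(list(
    species_id = species_id, presences = pres, selection = selection,
    climate = clim$result, soil = soil$result,
    climate_surface = clim$result$surface, soil_surface = soil$result$surface,
    dual_surface = dual_surface,
    climate_threshold = clim$result$mean_threshold,
    soil_threshold = soil$result$mean_threshold,
    climate_binary = climate_binary, soil_binary = soil_binary,
    dual_binary = dual_binary,
    climate_layers = selection$kept, soil_layers = soil_layers,
    masks = list(climate = clim$masks, soil = soil$masks),
    plan = plan, seed = seed),
    class = "species_result")
}

#' Constrain a parasite's suitability by its host
#'
#' Final parasite suitability is the per-cell minimum of the parasite's
#' climate surface, a soil surface (its own, or the host's — both readings
#' of an obligate system are supported) and the host's dual surface. The
#' final binary map is the co-suitable intersection of the corresponding
#' binary maps, so the parasite's range is nested inside the host's.
#'
#' @param parasite,host `species_result` objects from [run_species].
#' @param parasite_soil_source `"self"` or `"host"`.
#' @return the parasite `species_result` augmented with `final_surface`,
#'   `final_binary` and `host_species_id`.
#' @export
constrain_to_host <- function(parasite, host,
                              parasite_soil_source = c("self", "host")) {
  parasite_soil_source <- match.arg(parasite_soil_source)
  soil_surface <- if (parasite_soil_source == "self") parasite$soil_surface
                  else host$soil_surface
  soil_binary <- if (parasite_soil_source == "self") parasite$soil_binary
                 else host$soil_binary
  parasite$final_surface <- host_constrained_suitability(
    parasite$climate_surface, soil_surface, host$dual_surface)
  parasite$final_binary <- co_suitable_map(
    list(parasite$climate_binary, soil_binary, host$dual_binary))
  parasite$parasite_soil_source <- parasite_soil_source
  parasite$host_species_id <- host$species_id
  parasite
}

#' Project species results under climate scenarios
#'
#' Re-predicts the climate surfaces of both species with the ALREADY-FITTED
#' per-iteration ensembles on scenario-shifted stacks (no re-training), holds
#' the soil models static, rebuilds the minimum-rule surfaces, binarizes at
#' the thresholds of the current period, and accounts suitable areas per
#' region together with Schoener's D overlaps (host climate vs soil;
#' parasite climate vs host final; parasite climate vs parasite soil).
#'
#' @param host,parasite `species_result`s; `parasite` must have been passed
#'   through [constrain_to_host].
#' @param stack the unshifted [env_stack] used for fitting.
#' @param scenarios named list of [scenario_config]s including `"current"`.
#' @param region_masks named list of logical region matrices (default
#'   [default_region_masks]).
#' @return list with `area_table` (data.frame of species/scenario/region
#'   areas in 10^3 km^2 and percent change vs current) and `overlap_table`
#'   (data.frame of the three D values per scenario).
#' @export
run_scenarios <- function(host, parasite, stack, scenarios,
                          region_masks = default_region_masks(stack_geometry(stack))) {
  if (is.null(parasite$final_surface))
    stop("run_scenarios: run constrain_to_host() on the parasite first")
  if (!"current" %in% names(scenarios))
    stop("run_scenarios: scenarios must include 'current'")
  soil_source <- parasite$parasite_soil_source
  area_rows <- list(); overlap_rows <- list()
  areas_current <- list()
  for (sc_name in c("current", setdiff(names(scenarios), "current"))) {
    sc <- scenarios[[sc_name]]
    shifted <- apply_scenario(stack, sc)
    clim_h <- project_surface(host$climate$ensembles,
                              stack_subset(shifted, host$climate_layers))
    clim_p <- project_surface(parasite$climate$ensembles,
                              stack_subset(shifted, parasite$climate_layers))
    soil_h <- host$soil_surface
    soil_p <- if (soil_source == "self") parasite$soil_surface else soil_h
    dual_h <- min_overlay(list(clim_h, soil_h))
    final_p <- host_constrained_suitability(clim_p, soil_p, dual_h)
    bin_h <- co_suitable_map(list(binarize(clim_h, host$climate_threshold),
                                  host$soil_binary))
    soil_bin_p <- if (soil_source == "self") parasite$soil_binary
                  else host$soil_binary
    bin_p <- co_suitable_map(list(binarize(clim_p, parasite$climate_threshold),
                                  soil_bin_p, bin_h))
    for (rg in names(region_masks)) {
      for (sp in c("host", "parasite")) {
        a <- suitable_area(if (sp == "host") bin_h else bin_p,
                           region_masks[[rg]])
        key <- paste(sp, rg)
        if (sc_name == "current") areas_current[[key]] <- a
        area_rows[[length(area_rows) + 1L]] <- data.frame(
          species = if (sp == "host") host$species_id else parasite$species_id,
          scenario = sc_name, region = rg, area = a,
          percent_change = if (sc_name == "current") 0
                           else if (areas_current[[key]] > 0)
                             area_change(areas_current[[key]], a)
                           else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    overlap_rows[[length(overlap_rows) + 1L]] <- data.frame(
      scenario = sc_name,
      host_climate_soil_D = schoeners_d(clim_h, soil_h)$D,
      parasite_climate_host_D = schoeners_d(clim_p, dual_h)$D,
      parasite_climate_soil_D = schoeners_d(clim_p, soil_p)$D,
      stringsAsFactors = FALSE)
  }
  list(area_table = do.call(rbind, area_rows),
       overlap_table = do.call(rbind, overlap_rows))
}
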