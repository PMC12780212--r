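#' Rasterize classed road features with precedence
#'
#' Roads carry a `road_class` attribute (1 primary, 2 secondary, 3
#' tertiary/country). Where classes overlap on a pixel the highest class
#' (lowest number) wins, so the raster can feed the speed-surface
#' precedence directly.
#'
#' @param roads Line [feature_set()] with a `road_class` column.
#' @param grid Target [grid_spec()].
#' @return Categorical `hf_raster` with codes 0 (none), 1, 2, 3.
#' @export
rasterize_road_classes <- function(roads, grid) {
  if (n_features(roads) == 0)
    return(raster_layer(matrix(0, grid$n_rows, grid$n_cols), grid,
                        kind = "categorical"))
  prio <- rasterize(dplyr::mutate(roads, prio = 4 - .data$road_class),
                    grid, burn = "prio")
  v <- raster_values(prio)
  raster_layer(ifelse(v > 0, 4 - v, 0), grid, kind = "categorical")
}

#' Default per-pressure maxima
#'
#' The normalization ceiling of each pressure: the highest dataset maximum
#' score contributing to it (indirect pressure peaks at 4 by
#' construction). Used to normalize both sides of the validation
#' comparison.
#'
#' @param lu_max Maximum of the LULC pressure (5.5 with Peru pasture; 5.25
#'   for a unified Ecuador-style configuration).
#' @return Named numeric vector over the eight pressures.
#' @export
default_pressure_maxima <- function(lu_max = 5.5) {
  c(BE = 10, LU = lu_max, PD = 10, IND = 4, RR = 8.75, EI = 10, OG = 10,
    M = 7.25)
}

#' Standard dataset configuration for a synthetic landscape
#'
#' Expresses a generated landscape as the standard list of scored datasets
#' (the Peru-style configuration of the default scores): urban areas and
#' settlements (BE), agriculture/pasture/plantations (LU), population
#' counts (PD), radiance plus power points (EI), roads, trails and railway
#' (RR), wells, refineries, filling stations and pipelines (OG), and mines
#' (M).
#'
#' @param ls An `hf_landscape` from [generate_landscape()].
#' @return A list of [hf_dataset()] entries.
#' @export
landscape_datasets <- function(ls) {
  codes <- hf_lulc_codes()
  fs <- default_feature_scores()
  sc <- function(id) fs$score[fs$dataset == id]
  rad <- function(id) fs$radius_m[fs$dataset == id]
  roads <- ls$features$roads
  road_ds <- purrr::map(c(primary = 1, secondary = 2, country = 3),
                        function(cl) roads[roads$road_class == cl, ])
  datasets <- list(
    hf_dataset("urban_areas", "BE", "direct", ls$lulc,
               params = list(mapping = stats::setNames(
                 sc("urban"), codes[["urban"]]))),
    hf_dataset("settlements", "BE", "point_approx", ls$features$settlements,
               params = list(score = sc("settlement"), s0 = 4,
                             max_dist = 100)),
    hf_dataset("lulc", "LU", "direct", ls$lulc,
               params = list(mapping = stats::setNames(
                 c(sc("agriculture_peru"), sc("pasture_peru"),
                   sc("tree_plantation")),
                 codes[c("agriculture", "pasture", "plantation")])),
               multitemporal = FALSE),
    hf_dataset("population", "PD", "log_count", ls$population,
               national = FALSE),
    hf_dataset("ntl", "EI", "linear", ls$radiance, national = FALSE),
    hf_dataset("power_points", "EI", "point_actual",
               ls$features$power_points,
               params = list(score = sc("electrical_point"),
                             radius = rad("electrical_point"))),
    hf_dataset("roads_primary", "RR", "direct",
               restore_features(road_ds$primary, roads),
               params = list(score = sc("road_primary"))),
    hf_dataset("roads_secondary", "RR", "direct",
               restore_features(road_ds$secondary, roads),
               params = list(score = sc("road_secondary"))),
    hf_dataset("roads_country", "RR", "direct",
               restore_features(road_ds$country, roads),
               params = list(score = sc("road_country"))),
    hf_dataset("trails", "RR", "direct", ls$features$trails,
               params = list(score = sc("trail"))),
    hf_dataset("railway", "RR", "direct", ls$features$railway,
               params = list(score = sc("railway"))),
    hf_dataset("wells", "OG", "point_actual", ls$features$wells,
               params = list(score = sc("well"), radius = rad("well"))),
    hf_dataset("refineries", "OG", "point_actual", ls$features$refineries,
               params = list(score = sc("refinery"),
                             radius = rad("refinery"))),
    hf_dataset("filling_stations", "OG", "point_actual",
               ls$features$filling_stations,
               params = list(score = sc("filling_station"),
                             radius = rad("filling_station"))),
    hf_dataset("mines", "M", "point_actual", ls$features$mines,
               params = list(score = sc("mining"), radius = rad("mining")))
  )
  # drop empty feature datasets (e.g. a zero-urban landscape)
  keep <- purrr::map_lgl(datasets, function(d)
    !inherits(d$data, "hf_features") || n_features(d$data) > 0)
  datasets[keep]
}

# subsetting a tibble drops the hf_features attributes; restore them
restore_features <- function(sub, template) {
  structure(sub, kind = attr(template, "kind"), crs = attr(template, "crs"),
            class = class(template))
}

#' Indirect-pressure layer of a synthetic landscape
#'
#' Runs the full accessibility chain on a landscape bundle: speed surface
#' under the precedence rules, per-pixel crossing time, source extraction
#' from built environments (urban pixels plus rasterized settlements,
#' clusters of two or more pixels), least-cost travel time, and
#' exponential-decay scoring over the 4-hour horizon.
#'
#' @param ls An `hf_landscape`.
#' @param model A [speed_model()].
#' @param s0,t_max,floor Decay parameters, see [score_indirect()].
#' @param n_tiles Optional `c(rows, cols)` to run the tiled computation.
#' @param overlap_m Tile overlap in meters (tiled mode).
#' @return List with `indirect` (scored `hf_raster`), `traveltime`
#'   (`hf_traveltime`), `speed` and `sources`.
#' @export
landscape_indirect <- function(ls, model = speed_model(), s0 = 4, t_max = 4,
                               floor = 0.1, n_tiles = NULL,
                               overlap_m = 100e3) {
  codes <- hf_lulc_codes()
  roads_r <- rasterize_road_classes(ls$features$roads, ls$grid)
  ww <- rasterize(ls$features$waterways, ls$grid, burn = 1)
  coast <- if (n_features(ls$features$coastline) > 0)
    rasterize(ls$features$coastline, ls$grid, burn = 1) else NULL
  speed <- build_speed_surface(ls$lulc, ls$slope, ls$elevation,
                               roads = roads_r, waterways = ww,
                               coastline = coast, model = model)
  built <- raster_values(ls$lulc) == codes[["urban"]]
  if (n_features(ls$features$settlements) > 0) {
    sp <- rasterize(ls$features$settlements, ls$grid, burn = 1)
    built <- built | raster_values(sp) != 0
  }
  sources <- extract_sources(raster_layer(built * 1, ls$grid))
  cost <- pixel_crossing_time(speed)
  # built environments carry null traversal cost
  cv <- raster_values(cost)
  cv[raster_values(sources) != 0] <- 0
  cost <- raster_layer(cv, ls$grid)
  tt <- if (is.null(n_tiles)) least_cost_time(cost, sources)
        else tiled_least_cost(cost, sources, n_tiles = n_tiles,
                              overlap_m = overlap_m)
  list(indirect = score_indirect(tt, s0 = s0, t_max = t_max, floor = floor),
       traveltime = tt, speed = speed, sources = sources)
}

#' Generate synthetic visual-truth scores for validation plots
#'
#' Stands in for human photo interpretation on synthetic data. For each
#' plot and pressure the true pressure level is read from the pressure
#' layers. With `quantize = FALSE` (the default) the generator emits
#' continuous 0-3 scores that invert the standardization exactly, so a
#' noiseless run reproduces the map-side index to numerical precision —
#' the full-protocol recovery check. With `quantize = TRUE` scores pass
#' through the interpreter's coverage bands ([visual_area_score()]) and
#' the indirect pressure collapses to a presence flag, emulating the
#' information loss of real visual scoring. Gaussian noise of `noise_sd`
#' (on the 0-3 score scale) then perturbs the scores, clamped to range.
#'
#' @param plots Plot tibble from [draw_plots()].
#' @param pressures List of `hf_pressure` layers (see [pressure_layers()]).
#' @param max_scores Named per-pressure maxima, see
#'   [default_pressure_maxima()].
#' @param noise_sd Interpreter noise (standard deviation on the 0-3
#'   scale); 0 = perfect interpreter.
#' @param seed Integer seed for the noise.
#' @param quantize Apply the banded visual scoring (see above).
#' @param reduce Plot extraction rule, see [extract_plot_pressures()].
#' @return Long tibble with `plot_id`, `pressure`, `kind`, `score`.
#' @export
generate_visual_truth <- function(plots, pressures, max_scores,
                                  noise_sd = 0, seed = 1, quantize = FALSE,
                                  reduce = "center") {
  truth <- extract_plot_pressures(plots, pressures, reduce = reduce)
  truth$max <- max_scores[truth$pressure]
  set.seed(seed)
  if (quantize) {
    cov_frac <- pmin(pmax(truth$value / truth$max, 0), 1)
    score <- ifelse(truth$pressure == "IND",
                    as.numeric(truth$value > 0),
                    as.numeric(visual_area_score(cov_frac)))
    kind <- ifelse(truth$pressure == "IND", "indirect", "area")
    if (noise_sd > 0) {
      flip <- stats::rnorm(length(score), sd = noise_sd)
      score <- ifelse(kind == "indirect",
                      ifelse(abs(flip) > 1, 1 - score, score),
                      pmin(pmax(round(score + flip), 0), 3))
    }
  } else {
    score <- 3 * truth$value / truth$max
    kind <- rep("area", nrow(truth))
    if (noise_sd > 0)
      score <- pmin(pmax(score + stats::rnorm(length(score),
                                              sd = noise_sd), 0), 3)
  }
  tibble::tibble(plot_id = truth$plot_id, pressure = truth$pressure,
                 kind = kind, score = score)
}
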