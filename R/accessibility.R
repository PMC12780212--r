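#' The precedence-ordered travel speed model
#'
#' Speeds (km/h) used to build the friction surface for the accessibility
#' analysis, in strict precedence: roads (primary 60, secondary 40,
#' tertiary/country 30), coastline navigation (20), waterway navigation (a
#' 5 x 5 matrix over slope and elevation bands), walking across agriculture
#' (`a * slope^b`), and walking through natural vegetation
#' (`c * ln(slope) + d`, halved when flooded). Slope is clamped to >= 1 %
#' before the walking formulas (both diverge as slope tends to 0) and
#' natural-vegetation walking is floored at `min_walk` km/h.
#'
#' @param roads Named vector of road speeds.
#' @param coastline Coastline navigation speed.
#' @param waterway_matrix 5 x 5 speed matrix; rows are elevation bands
#'   (breaks 450, 700, 1800, 2800 m), columns slope bands (breaks 5, 10,
#'   15, 25 %).
#' @param ag_coef Power-law coefficients (a, b) for agriculture walking.
#' @param nat_coef Log-law coefficients (c, d) for natural vegetation.
#' @param flooded_divisor Divisor applied in flooded natural vegetation.
#' @param min_walk Floor (km/h) for walking speeds.
#' @param slope_clamp Minimum slope (%) fed to the walking formulas.
#' @return An object of class `hf_speed_model`.
#' @export
speed_model <- function(roads = c(primary = 60, secondary = 40, tertiary = 30),
                        coastline = 20,
                        waterway_matrix = default_waterway_speeds(),
                        ag_coef = c(a = 10.560326, b = -0.199553),
                        nat_coef = c(c = -0.975931, d = 6.761258),
                        flooded_divisor = 2,
                        min_walk = 0.1, slope_clamp = 1) {
  stopifnot(all(roads > 0), coastline > 0, all(waterway_matrix > 0),
            identical(dim(waterway_matrix), c(5L, 5L)),
            flooded_divisor > 0, min_walk > 0, slope_clamp > 0)
  structure(list(roads = roads, coastline = coastline,
                 waterway_matrix = waterway_matrix,
                 ag_coef = ag_coef, nat_coef = nat_coef,
                 flooded_divisor = flooded_divisor,
                 min_walk = min_walk, slope_clamp = slope_clamp,
                 slope_breaks = c(5, 10, 15, 25),
                 elev_breaks = c(450, 700, 1800, 2800)),
            class = "hf_speed_model")
}

#' @rdname speed_model
#' @export
default_waterway_speeds <- function() {
  m <- rbind(
    c(15,  7.5, 3.8, 1.9, 1.4),   # elevation < 450 m
    c(7.5, 3.9, 2.7, 1.9, 1.4),   # 450 - 700
    c(3.8, 2.7, 2.0, 1.7, 1.4),   # 700 - 1800
    c(1.9, 1.9, 1.7, 1.4, 1.3),   # 1800 - 2800
    c(1.4, 1.4, 1.4, 1.3, 1.2))   # > 2800
  dimnames(m) <- list(elevation = c("<450", "450-700", "700-1800",
                                    "1800-2800", ">2800"),
                      slope = c("<5", "5-10", "10-15", "15-25", ">25"))
  m
}

#' Walking speed across agricultural land
#'
#' @param slope_pct Slope in percent (clamped to >= `slope_clamp`).
#' @param model A [speed_model()].
#' @return Speed in km/h.
#' @export
speed_walk_agriculture <- function(slope_pct, model = speed_model()) {
  s <- pmax(slope_pct, model$slope_clamp)
  model$ag_coef[["a"]] * s^model$ag_coef[["b"]]
}

#' Walking speed through natural vegetation
#'
#' @inheritParams speed_walk_agriculture
#' @param flooded Logical; flooded vegetation halves the speed.
#' @return Speed in km/h, floored at `model$min_walk`.
#' @export
speed_walk_natural <- function(slope_pct, flooded = FALSE,
                               model = speed_model()) {
  s <- pmax(slope_pct, model$slope_clamp)
  v <- model$nat_coef[["c"]] * log(s) + model$nat_coef[["d"]]
  flooded <- rep_len(flooded, length(v))
  v[flooded] <- v[flooded] / model$flooded_divisor
  pmax(v, model$min_walk)
}

#' Waterway navigation speed
#'
#' Band lookup in the slope x elevation speed matrix.
#'
#' @inheritParams speed_walk_agriculture
#' @param elevation_m Elevation in meters above sea level.
#' @return Speed in km/h.
#' @export
speed_waterway <- function(slope_pct, elevation_m, model = speed_model()) {
  si <- findInterval(slope_pct, model$slope_breaks) + 1
  ei <- findInterval(elevation_m, model$elev_breaks) + 1
  model$waterway_matrix[cbind(ei, si)]
}

#' Build the speed surface
#'
#' Assigns every pixel the speed of the first applicable rule in precedence
#' order: roads > coastline > waterways > agriculture walking > natural
#' vegetation walking. Water pixels carrying no navigable line are barriers
#' (`NA` speed). Source (built-environment) pixels are left untouched here;
#' they get zero crossing cost downstream.
#'
#' @param lulc Categorical `hf_raster` coded per [hf_lulc_codes()].
#' @param slope Continuous `hf_raster`, percent rise.
#' @param elevation Continuous `hf_raster`, meters.
#' @param roads Categorical `hf_raster`: 1 primary, 2 secondary, 3
#'   tertiary/country, 0/NA none. Optional.
#' @param waterways,coastline Binary `hf_raster`s of navigable lines.
#'   Optional.
#' @param model A [speed_model()].
#' @return A continuous `hf_raster` of speeds in km/h (`NA` = barrier).
#' @export
build_speed_surface <- function(lulc, slope, elevation, roads = NULL,
                                waterways = NULL, coastline = NULL,
                                model = speed_model()) {
  check_same_grid(lulc, slope, elevation, what = "speed-surface inputs")
  codes <- hf_lulc_codes()
  lc <- raster_values(lulc)
  sl <- raster_values(slope)
  el <- raster_values(elevation)
  v <- matrix(NA_real_, nrow(lc), ncol(lc))

  natural <- !is.na(lc) & lc %in% codes[c("forest", "shrub")]
  v[natural] <- speed_walk_natural(sl[natural], flooded = FALSE, model)
  flooded <- !is.na(lc) & lc == codes[["flooded_forest"]]
  v[flooded] <- speed_walk_natural(sl[flooded], flooded = TRUE, model)
  ag <- !is.na(lc) &
    lc %in% codes[c("agriculture", "pasture", "plantation", "urban")]
  v[ag] <- speed_walk_agriculture(sl[ag], model)

  water <- !is.na(lc) & lc == codes[["water"]]
  v[water] <- NA_real_  # barrier unless a navigable line covers the pixel
  if (!is.null(waterways)) {
    check_same_grid(lulc, waterways)
    on <- !is.na(raster_values(waterways)) & raster_values(waterways) != 0
    v[on] <- speed_waterway(sl[on], el[on], model)
  }
  if (!is.null(coastline)) {
    check_same_grid(lulc, coastline)
    on <- !is.na(raster_values(coastline)) & raster_values(coastline) != 0
    v[on] <- model$coastline
  }
  if (!is.null(roads)) {
    check_same_grid(lulc, roads)
    rd <- raster_values(roads)
    v[!is.na(rd) & rd == 3] <- model$roads[["tertiary"]]
    v[!is.na(rd) & rd == 2] <- model$roads[["secondary"]]
    v[!is.na(rd) & rd == 1] <- model$roads[["primary"]]
  }
  raster_layer(v, attr(lulc, "grid"), kind = "continuous")
}

#' Per-pixel crossing time
#'
#' Time (hours) to traverse one pixel horizontally or vertically:
#' `pixel_size / speed`. Barrier pixels stay `NA`.
#'
#' @param speed Speed surface from [build_speed_surface()] (km/h).
#' @return A continuous `hf_raster` of hours per pixel crossing.
#' @export
pixel_crossing_time <- function(speed) {
  g <- attr(speed, "grid")
  v <- raster_values(speed)
  if (any(v[!is.na(v)] <= 0))
    stop("speeds must be positive (use NA for barriers)", call. = FALSE)
  raster_layer((g$pixel_size / 1000) / v, g, kind = "continuous")
}

#' Extract accessibility sources from built environments
#'
#' Keeps 8-connected clusters of at least `min_cluster` pixels, dropping
#' isolated single pixels that are too small to indicate habitation.
#'
#' @param built_env Binary `hf_raster` of built-environment pixels.
#' @param min_cluster Minimum cluster size (default 2).
#' @return Binary `hf_raster` source mask.
#' @export
extract_sources <- function(built_env, min_cluster = 2) {
  cl <- connected_clusters(built_env, connectivity = 8)
  keep <- cl$sizes$cluster[cl$sizes$n_pixels >= min_cluster]
  if (!length(keep))
    stop("no built-environment cluster reaches the minimum size of ",
         min_cluster, " pixels; there are no accessibility sources",
         call. = FALSE)
  lab <- raster_values(cl$labels)
  raster_like(matrix((lab %in% keep) * 1, nrow(lab), ncol(lab)), built_env,
              kind = "continuous")
}

#' Least-cost travel time from sources
#'
#' Multi-source shortest-path accumulation over the 4-connected pixel graph
#' (moves are horizontal or vertical, matching the per-pixel crossing-time
#' definition). The step cost between adjacent pixels is the mean of their
#' crossing times; source pixels enter the queue at time 0, and giving
#' built environments a null crossing cost (the "speed 0" convention read
#' as zero traversal time) is done upstream by zeroing the cost raster on
#' the source mask, as [landscape_indirect()] does. Pixels cut off by
#' barriers come back as `Inf`.
#'
#' @param cost Crossing-time `hf_raster` from [pixel_crossing_time()].
#' @param sources Binary `hf_raster` source mask (see [extract_sources()]).
#' @return An object of class `hf_traveltime`: list of `grid`, `hours`
#'   (matrix) and `sources`.
#' @export
least_cost_time <- function(cost, sources) {
  g <- check_same_grid(cost, sources, what = "cost and sources")
  src <- raster_values(sources)
  src <- !is.na(src) & src != 0
  if (!any(src)) stop("source mask is empty", call. = FALSE)
  cv <- raster_values(cost)
  if (any(cv[!is.na(cv) & !src] <= 0))
    stop("off-source crossing costs must be positive", call. = FALSE)
  hours <- grid_dijkstra(cv, src)
  structure(list(grid = g, hours = hours, sources = src),
            class = "hf_traveltime")
}

#' @export
print.hf_traveltime <- function(x, ...) {
  fin <- x$hours[is.finite(x$hours)]
  cat(sprintf(
    "<hf_traveltime> %s  %d source px  reachable: %d  max %.2f h\n",
    format(x$grid), sum(x$sources), length(fin),
    if (length(fin)) max(fin) else NA))
  invisible(x)
}

#' Tiled least-cost travel time
#'
#' Computes travel time per overlapping tile and mosaics tiles by the
#' pixelwise minimum — the memory-bounded strategy used for country-scale
#' runs, where tiles overlap generously (100 km and more) so that shortest
#' paths rarely leave a tile. With overlap spanning the whole grid the
#' result equals the untiled computation exactly; with less overlap it can
#' only overestimate, never underestimate.
#'
#' @inheritParams least_cost_time
#' @param n_tiles Integer vector `c(rows, cols)` of tile counts.
#' @param overlap_m Overlap between adjacent tiles, meters.
#' @param min_overlap_m Smallest admissible overlap (guardrail; default one
#'   pixel).
#' @return An `hf_traveltime`.
#' @export
tiled_least_cost <- function(cost, sources, n_tiles = c(2, 2),
                             overlap_m = 100e3, min_overlap_m = NULL) {
  g <- check_same_grid(cost, sources, what = "cost and sources")
  min_overlap_m <- min_overlap_m %||% g$pixel_size
  if (overlap_m < min_overlap_m)
    stop("tile overlap below the configured minimum", call. = FALSE)
  ov <- ceiling(overlap_m / g$pixel_size)
  rows <- tile_ranges(g$n_rows, n_tiles[1], ov)
  cols <- tile_ranges(g$n_cols, n_tiles[2], ov)
  covered_r <- sort(unique(unlist(lapply(rows, function(r) r[1]:r[2]))))
  covered_c <- sort(unique(unlist(lapply(cols, function(r) r[1]:r[2]))))
  if (!identical(covered_r, seq_len(g$n_rows)) ||
      !identical(covered_c, seq_len(g$n_cols)))
    stop("tile plan does not cover the grid", call. = FALSE)
  src <- raster_values(sources); src <- !is.na(src) & src != 0
  cv <- raster_values(cost)
  hours <- matrix(Inf, g$n_rows, g$n_cols)
  for (rr in rows) for (cc in cols) {
    ri <- rr[1]:rr[2]; ci <- cc[1]:cc[2]
    sub_src <- src[ri, ci, drop = FALSE]
    if (!any(sub_src)) next
    sub <- grid_dijkstra(cv[ri, ci, drop = FALSE], sub_src)
    hours[ri, ci] <- pmin(hours[ri, ci], sub)
  }
  structure(list(grid = g, hours = hours, sources = src),
            class = "hf_traveltime")
}

tile_ranges <- function(n, k, overlap) {
  edges <- floor(seq(0, n, length.out = k + 1))
  lapply(seq_len(k), function(i) {
    c(max(1, edges[i] + 1 - overlap), min(n, edges[i + 1] + overlap))
  })
}

#' Score indirect pressure from travel time
#'
#' Converts a travel-time surface into the indirect-pressure layer: scores
#' decay exponentially from `s0` (4, the natural-cover-loss threshold) at
#' the sources down to `floor` at the travel-time horizon `t_max` (4 h, a
#' routine daily travel budget), and are 0 beyond it. Unreachable pixels
#' score 0.
#'
#' @param tt An `hf_traveltime`.
#' @param s0 Score at zero travel time.
#' @param t_max Travel-time horizon in hours.
#' @param floor Score at `t_max`.
#' @return A continuous `hf_raster` in \[0, s0\].
#' @export
score_indirect <- function(tt, s0 = 4, t_max = 4, floor = 0.1) {
  stopifnot(inherits(tt, "hf_traveltime"))
  h <- tt$hours
  s <- score_exponential_decay(h, s0 = s0, max_dist = t_max, floor = floor)
  s[!is.finite(h)] <- 0
  raster_layer(s, tt$grid, kind = "continuous")
}
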