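#' The criterion-weighted scoring template
#'
#' Every pressure dataset is scored against four impact criteria — loss of
#' original cover, surface imperviousness, habitat viability/passage, and
#' pollution risk — whose importances sum to 10. A dataset's maximum score
#' is the importance-weighted sum of its four qualifications in \[0, 1\],
#' so no dataset can exceed 10 and a score of 4 or more signals loss of
#' the original ecosystem.
#'
#' @param ci Named numeric vector of the four criterion importances, in
#'   order (cover loss, imperviousness, habitat viability, pollution risk).
#'   Must be positive and sum to 10.
#' @return An object of class `hf_template`.
#' @examples
#' dataset_max_score(c(1, 0.75, 0.5, 0.25))  # settlements, ports: 7.5
#' @export
scoring_template <- function(ci = c(cover_loss = 4, imperviousness = 3,
                                    habitat_viability = 2,
                                    pollution_risk = 1)) {
  if (length(ci) != 4 || any(ci <= 0) || abs(sum(ci) - 10) > 1e-9)
    stop("criterion importances must be 4 positive values summing to 10",
         call. = FALSE)
  structure(list(ci = ci), class = "hf_template")
}

#' @export
print.hf_template <- function(x, ...) {
  cat("<hf_template> criterion importances:",
      paste(sprintf("%s=%g", names(x$ci), x$ci), collapse = ", "), "\n")
  invisible(x)
}

#' Maximum score of a dataset from its criterion qualifications
#'
#' @param q Numeric vector of four qualifications in \[0, 1\], or a matrix /
#'   data frame with four columns (one row per dataset).
#' @param template A [scoring_template()].
#' @return Numeric score(s) in \[0, 10\].
#' @export
dataset_max_score <- function(q, template = scoring_template()) {
  qm <- if (is.null(dim(q))) matrix(q, nrow = 1) else as.matrix(q)
  if (ncol(qm) != 4) stop("expected four qualifications", call. = FALSE)
  if (any(qm < 0 | qm > 1))
    stop("qualifications must lie in [0, 1]", call. = FALSE)
  as.numeric(qm %*% template$ci)
}

#' The reference dataset scoring table
#'
#' The seventeen dataset rows of the national HF scoring template: pressure
#' membership, the four criterion qualifications, and the maximum score
#' computed from them via [dataset_max_score()] (never hard-coded).
#'
#' Pressure codes: BE built environments, LU land use/land cover, PD
#' population density, IND indirect, RR roads and railways, EI electrical
#' infrastructure, OG oil and gas, M mining.
#'
#' @param template A [scoring_template()].
#' @return A tibble with columns `pressure`, `dataset`, `q_cover_loss`,
#'   `q_imperviousness`, `q_habitat`, `q_pollution`, `max_score`.
#' @export
hf_score_table <- function(template = scoring_template()) {
  rows <- tibble::tribble(
    ~pressure,  ~dataset,                                   ~q1,  ~q2,  ~q3,  ~q4,
    "BE",       "urban_areas",                               1,    1,    1,    1,
    "PD; EI",   "densely_populated_illuminated_areas",       1,    1,    1,    1,
    "OG",       "wells_depots_refineries_stations",          1,    1,    1,    1,
    "EI",       "power_plants_dams_substations_towers",      1,    1,    1,    0,
    "RR; BE",   "primary_roads_railways_runways",            1,    1, 0.75, 0.25,
    "EI",       "solar_power_hydroelectric_plants",          1, 0.75,    1,    0,
    "RR",       "secondary_roads",                           1,    1,  0.5, 0.25,
    "BE",       "settlements_ports_sparse_houses",           1, 0.75,  0.5, 0.25,
    "M",        "mining_areas",                              1, 0.25, 0.75,    1,
    "LU",       "artificial_water_bodies",                   1,    0,    1,    0,
    "RR",       "country_roads",                             1,  0.5, 0.25,    0,
    "LU",       "pasture",                                   1,    0, 0.75,    0,
    "LU",       "agriculture",                               1,    0,  0.5, 0.25,
    "OG",       "pipelines",                                 1,    0,  0.5, 0.25,
    "EI",       "transmission_power_lines",                  1,    0,  0.5,    0,
    "LU",       "tree_plantations",                          1,    0, 0.25,    0,
    "RR",       "trails",                                    0, 0.25, 0.25,    0
  )
  rows$max_score <- dataset_max_score(rows[, c("q1", "q2", "q3", "q4")],
                                      template)
  dplyr::rename(rows, q_cover_loss = "q1", q_imperviousness = "q2",
                q_habitat = "q3", q_pollution = "q4")
}

#' Default category and feature scores
#'
#' The shipped direct-score lookup reproducing the national configuration:
#' urban 10, runways 8.75, settlements/ports/sparse houses 7.5, Peru
#' pasture 5.5 and agriculture 5.25 (Ecuador uses a unified 5.25), tree
#' plantations 4.5, primary roads/railways 8.75, secondary 8.25, country
#' roads 6, trails 1.25, pipelines 5.25, transmission lines 5, electrical
#' point features 9 (8.25 for generation plants) at 50 m, wells 10 at 50 m,
#' filling stations 10 at 150 m, refineries/deposits 10 at 500 m, mining
#' 7.25 (50 m around point data).
#'
#' @return A tibble with `dataset`, `pressure`, `score`, and `radius_m`
#'   (NA where not a point-buffer case).
#' @export
default_feature_scores <- function() {
  tibble::tribble(
    ~dataset,               ~pressure, ~score, ~radius_m,
    "urban",                "BE",      10,     NA,
    "runway",               "BE",      8.75,   NA,
    "sparse_houses",        "BE",      7.5,    NA,
    "settlement",           "BE",      7.5,    NA,
    "pasture_peru",         "LU",      5.5,    NA,
    "agriculture_peru",     "LU",      5.25,   NA,
    "lulc_ecuador",         "LU",      5.25,   NA,
    "tree_plantation",      "LU",      4.5,    NA,
    "road_primary",         "RR",      8.75,   NA,
    "railway",              "RR",      8.75,   NA,
    "road_secondary",       "RR",      8.25,   NA,
    "road_country",         "RR",      6,      NA,
    "trail",                "RR",      1.25,   NA,
    "pipeline",             "OG",      5.25,   NA,
    "transmission_line",    "EI",      5,      NA,
    "electrical_point",     "EI",      9,      50,
    "electrical_plant",     "EI",      8.25,   50,
    "well",                 "OG",      10,     50,
    "filling_station",      "OG",      10,     150,
    "refinery",             "OG",      10,     500,
    "mining",               "M",       7.25,   50
  )
}

#' Valid pressure identifiers
#' @return Character vector of the eight pressure codes.
#' @export
hf_pressures <- function() c("BE", "LU", "PD", "IND", "RR", "EI", "OG", "M")

#' Score a categorical raster by direct lookup
#'
#' Scoring case for layers organized in categories (LULC classes, rasterized
#' linear features): every pixel of a mapped category receives its score at
#' the direct location; unmapped categories score 0.
#'
#' @param raster Categorical (or binary) `hf_raster`.
#' @param mapping Named numeric vector (names are category codes) or a data
#'   frame with columns `category` and `score`. Scores must lie in
#'   \[0, 10\].
#' @return A continuous `hf_raster` in \[0, 10\]; `NA` propagates.
#' @export
score_direct <- function(raster, mapping) {
  if (is.data.frame(mapping)) {
    m <- mapping$score
    names(m) <- mapping$category
    mapping <- m
  }
  if (any(mapping > 10) || any(mapping < 0))
    stop("mapped scores must lie in [0, 10]", call. = FALSE)
  v <- raster_values(raster)
  out <- matrix(0, nrow(v), ncol(v))
  out[is.na(v)] <- NA_real_
  for (cat in names(mapping)) out[!is.na(v) & v == as.numeric(cat)] <- mapping[[cat]]
  raster_like(out, raster, kind = "continuous")
}

#' Exponential distance-decay scoring
#'
#' Scoring case for influence that is most intense at the source and decays
#' rapidly with distance: `s(d) = S0 * exp(-d * log(S0 / floor) / D)` for
#' `d <= D` and 0 beyond, so `s(0) = S0` and `s(D) = floor`. Used for the
#' halo around approximate point locations (S0 = 4 to 100 m) and, over
#' travel time, for the indirect-pressure layer (S0 = 4 to 4 h).
#'
#' @param distance Continuous `hf_raster` (or bare numeric) of nonnegative
#'   distances — meters or hours, any unit shared with `max_dist`.
#' @param s0 Score at distance 0, in (0, 10\].
#' @param max_dist Decay horizon D (> 0), same unit as `distance`.
#' @param floor Score reached exactly at D, in (0, s0).
#' @return Same shape as `distance`, scores in \[0, s0\].
#' @export
score_exponential_decay <- function(distance, s0, max_dist, floor = 0.1) {
  if (!is.numeric(max_dist) || max_dist <= 0)
    stop("`max_dist` must be positive", call. = FALSE)
  stopifnot(s0 > 0, s0 <= 10, floor > 0, floor < s0)
  f <- function(d) {
    s <- s0 * exp(-d * log(s0 / floor) / max_dist)
    s[d > max_dist] <- 0
    s
  }
  if (inherits(distance, "hf_raster"))
    raster_like(f(raster_values(distance)), distance, kind = "continuous")
  else f(distance)
}

#' Logarithmic scoring of population counts
#'
#' `score = coeff * log10(count + 1)`, capped at 10; counts above
#' `cap_threshold` (70 persons per 30 m pixel by default, the upper range
#' of dense city pixels) score 10 outright. The base-10 logarithm with
#' coefficient 5.41 puts the threshold itself at ~10.
#'
#' @param count `hf_raster` (or numeric) of nonnegative person counts.
#' @param coeff Log coefficient (default 5.41).
#' @param cap_threshold Count above which the score saturates at 10.
#' @return Scores in \[0, 10\].
#' @export
score_log_count <- function(count, coeff = 5.41, cap_threshold = 70) {
  f <- function(v) {
    if (any(v[!is.na(v)] < 0))
      stop("population counts must be nonnegative", call. = FALSE)
    s <- pmin(coeff * log10(v + 1), 10)
    s[!is.na(v) & v > cap_threshold] <- 10
    s
  }
  if (inherits(count, "hf_raster"))
    raster_like(f(raster_values(count)), count, kind = "continuous")
  else f(count)
}

#' Logarithmic scoring of population density
#'
#' `score = coeff * log10(density + 1)`, capped at 10.
#'
#' @param density `hf_raster` (or numeric) of nonnegative densities.
#' @param coeff Log coefficient (default 2.5).
#' @return Scores in \[0, 10\].
#' @export
score_log_density <- function(density, coeff = 2.5) {
  f <- function(v) {
    if (any(v[!is.na(v)] < 0))
      stop("population densities must be nonnegative", call. = FALSE)
    pmin(coeff * log10(v + 1), 10)
  }
  if (inherits(density, "hf_raster"))
    raster_like(f(raster_values(density)), density, kind = "continuous")
  else f(density)
}

#' Linear scoring between two thresholds
#'
#' Scoring case for pressures assumed proportional to the measured value,
#' used for nighttime-light radiance: values below `vmin` (0.5, the noise
#' cutoff) score 0, values at or above `vmax` (60, the bright-city ceiling)
#' score `smax`, and the ramp is linear in between.
#'
#' @param values `hf_raster` (or numeric).
#' @param vmin,vmax Lower exclusion and upper saturation thresholds
#'   (`vmax > vmin`).
#' @param smax Score at/above `vmax` (default 10).
#' @return Scores in \[0, smax\].
#' @export
score_linear <- function(values, vmin = 0.5, vmax = 60, smax = 10) {
  if (vmax <= vmin) stop("`vmax` must exceed `vmin`", call. = FALSE)
  f <- function(v) {
    s <- smax * (v - vmin) / (vmax - vmin)
    s[v < vmin] <- 0
    s[v >= vmax] <- smax
    s
  }
  if (inherits(values, "hf_raster"))
    raster_like(f(raster_values(values)), values, kind = "continuous")
  else f(values)
}

#' Score point features onto a grid
#'
#' Two scoring cases for point datasets. `"actual"` locations (wells,
#' refineries, filling stations, electrical plants, mines) burn the score
#' on every pixel whose center lies within `radius` of a point, sizing the
#' feature realistically. `"approx"` locations (settlements, ports) burn
#' the score on the point pixel only and surround it with an exponential
#' decay halo from `s0` (default 4) out to `max_dist` (default 100 m),
#' acknowledging positional uncertainty. Points outside the grid are
#' skipped with a warning.
#'
#' @param points A point [feature_set()].
#' @param grid Target [grid_spec()].
#' @param score Score at the feature, in \[0, 10\].
#' @param mode `"actual"` or `"approx"`.
#' @param radius Buffer radius in meters (actual mode; must be at least the
#'   pixel size).
#' @param s0,max_dist,floor Decay parameters (approx mode); see
#'   [score_exponential_decay()].
#' @return A continuous `hf_raster` in \[0, 10\].
#' @export
score_points <- function(points, grid, score, mode = c("actual", "approx"),
                         radius = NULL, s0 = 4, max_dist = 100, floor = 0.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(points, "hf_features"), attr(points, "kind") == "point",
            score >= 0, score <= 10)
  mask <- rasterize(points, grid, burn = 1)
  if (!any(raster_values(mask) != 0, na.rm = TRUE))
    return(raster_layer(0, grid, kind = "continuous"))
  d <- euclidean_distance(mask)
  if (mode == "actual") {
    if (is.null(radius) || radius < grid$pixel_size)
      stop("actual mode needs `radius` of at least one pixel", call. = FALSE)
    out <- ifelse(raster_values(d) <= radius, score, 0)
  } else {
    halo <- score_exponential_decay(raster_values(d), s0 = s0,
                                    max_dist = max_dist, floor = floor)
    out <- ifelse(raster_values(d) == 0, score, halo)
  }
  raster_layer(out, grid, kind = "continuous")
}
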