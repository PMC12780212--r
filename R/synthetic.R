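#' LULC category codes used by the synthetic landscape
#'
#' @return Named integer vector of category codes: forest, flooded_forest,
#'   shrub, agriculture, pasture, plantation, urban, water.
#' @export
hf_lulc_codes <- function() {
  c(forest = 1L, flooded_forest = 2L, shrub = 3L, agriculture = 4L,
    pasture = 5L, plantation = 6L, urban = 7L, water = 8L)
}

#' Parameters of the synthetic landscape generator
#'
#' Defaults describe a 15 km x 15 km Andean-piedmont-like desk-scale
#' study area: mostly forested, a human-use belt of agriculture and
#' pasture around a handful of towns, a hierarchical road network linking
#' them, log-normally clustered population and blurred radiance tracking
#' it, smooth terrain with slopes in percent, and scattered extractive
#' infrastructure.
#'
#' @param class_fractions Named target fractions of the eight LULC classes
#'   (must sum to 1).
#' @param n_extra_settlements Settlement points added around urban
#'   clusters (the cluster centroids themselves are always settlements).
#' @param n_wells,n_refineries,n_filling,n_mines,n_power Infrastructure
#'   point counts.
#' @param n_trails Trail segments.
#' @param relief_m Elevation range in meters.
#' @param terrain_smooth_px,field_smooth_px Gaussian smoothing radii
#'   (pixels) of the terrain and the LULC fields.
#' @param pop_max Approximate maximum person count per pixel (above the
#'   saturation threshold of the count scoring, so capping is exercised).
#' @param radiance_max Approximate maximum background radiance.
#' @param flare_radiance Radiance burned at gas-flare points (above the
#'   linear-scoring ceiling of 60).
#' @param coastline Whether to draw a navigable coastline along the left
#'   grid edge.
#' @return A named list of parameters.
#' @export
landscape_params <- function(class_fractions = c(forest = 0.40,
                                                 flooded_forest = 0.05,
                                                 shrub = 0.14,
                                                 water = 0.05,
                                                 agriculture = 0.15,
                                                 pasture = 0.10,
                                                 plantation = 0.05,
                                                 urban = 0.06),
                             n_extra_settlements = 8, n_wells = 8,
                             n_refineries = 1, n_filling = 3, n_mines = 3,
                             n_power = 4, n_trails = 6, relief_m = 3500,
                             terrain_smooth_px = 15, field_smooth_px = 10,
                             pop_max = 150, radiance_max = 55,
                             flare_radiance = 80, coastline = TRUE) {
  if (abs(sum(class_fractions) - 1) > 1e-6)
    stop("class fractions must sum to 1", call. = FALSE)
  if (any(class_fractions < 0)) stop("negative class fraction", call. = FALSE)
  as.list(environment())
}

smooth_field <- function(n_rows, n_cols, sigma) {
  # the Gaussian brush must fit inside the image; cap sigma on small grids
  sigma <- min(sigma, (min(n_rows, n_cols) - 3) / 7)
  f <- EBImage::gblur(matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols),
                      sigma = sigma)
  as.matrix(f)
}

rescale01 <- function(m) (m - min(m)) / (max(m) - min(m))

#' Generate a seeded synthetic landscape
#'
#' Builds a complete, internally consistent input bundle for the HF
#' pipeline: terrain (elevation and percent slope), categorical LULC whose
#' class fractions hit the requested targets (rank-based thresholding of
#' smoothed Gaussian fields), settlements derived from urban patches, a
#' hierarchical road network connecting them (plus trails and a railway),
#' steepest-descent waterways, an optional coastline, log-normally
#' clustered population, radiance blurred from population with gas-flare
#' hotspots, and extractive/energy infrastructure points. Deterministic
#' for a given seed.
#'
#' @param seed Integer seed.
#' @param grid Target [grid_spec()]; default 500 x 500 pixels at 30 m.
#' @param params See [landscape_params()].
#' @return An object of class `hf_landscape`: list with `grid`,
#'   `elevation`, `slope`, `lulc`, `population`, `radiance`, `water`,
#'   `features` (named list of [feature_set()]s), `params`, `seed`.
#' @export
generate_landscape <- function(seed, grid = grid_spec(500, 500),
                               params = landscape_params()) {
  set.seed(seed)
  nr <- grid$n_rows; nc <- grid$n_cols; n <- nr * nc
  codes <- hf_lulc_codes()
  fr <- params$class_fractions

  ## terrain
  elev_f <- smooth_field(nr, nc, params$terrain_smooth_px)
  elevation <- rescale01(elev_f) * params$relief_m
  slope <- slope_percent(elevation, grid$pixel_size)

  ## LULC: split human vs natural by one field, order classes within each
  ## side by a second field; rank thresholds hit the fractions exactly
  human_cl <- c("urban", "agriculture", "pasture", "plantation")
  natural_cl <- c("water", "flooded_forest", "forest", "shrub")
  H <- smooth_field(nr, nc, params$field_smooth_px)
  M <- smooth_field(nr, nc, params$field_smooth_px)
  lulc <- matrix(NA_real_, nr, nc)
  frac_h <- sum(fr[human_cl])
  rk <- rank(H, ties.method = "first")
  human <- rk > (1 - frac_h) * n
  lulc[human] <- assign_by_rank(H[human], fr[human_cl] / frac_h,
                                codes[human_cl])
  lulc[!human] <- assign_by_rank(M[!human], fr[natural_cl] / (1 - frac_h),
                                 codes[natural_cl])
  lulc_r <- raster_layer(lulc, grid, kind = "categorical")

  ## settlements: urban cluster centroids + clustered extras
  urb <- raster_layer((lulc == codes[["urban"]]) * 1, grid)
  cl <- connected_clusters(urb, connectivity = 8)
  lab <- raster_values(cl$labels)
  cents <- NULL
  if (nrow(cl$sizes) > 0) {
    cc <- pixel_centers(grid)
    cents <- t(vapply(cl$sizes$cluster, function(k) {
      cells <- which(lab == k)
      r <- ((cells - 1) %% nr) + 1; c <- ((cells - 1) %/% nr) + 1
      c(mean(cc$x[c]), mean(cc$y[r]))
    }, c(0, 0)))
  }
  settle_xy <- cents
  if (!is.null(cents) && params$n_extra_settlements > 0) {
    parents <- cents[sample(nrow(cents), params$n_extra_settlements,
                            replace = TRUE), , drop = FALSE]
    extras <- parents + matrix(stats::rnorm(2 * nrow(parents),
                                            sd = 20 * grid$pixel_size),
                               ncol = 2)
    extras[, 1] <- pmin(pmax(extras[, 1], grid$origin_x + grid$pixel_size),
                        grid$origin_x + (nc - 1) * grid$pixel_size)
    extras[, 2] <- pmin(pmax(extras[, 2],
                             grid$origin_y - (nr - 1) * grid$pixel_size),
                        grid$origin_y - grid$pixel_size)
    settle_xy <- rbind(cents, extras)
  }
  settlements <- feature_set("point",
                             if (is.null(settle_xy)) list()
                             else purrr::map(seq_len(nrow(settle_xy)),
                                             function(i) settle_xy[i, ]),
                             crs = grid$crs)

  ## road network: spanning tree over settlements, classed by length
  roads <- build_road_network(settle_xy, grid)
  trails <- build_trails(settle_xy, grid, params$n_trails)
  railway <- build_railway(settle_xy, grid)

  ## waterways: steepest-descent polylines from high ground
  waterways <- build_waterways(elevation, grid, n_rivers = 3)
  coast <- if (isTRUE(params$coastline)) {
    x0 <- grid$origin_x + 0.5 * grid$pixel_size
    feature_set("line", list(rbind(
      c(x0, grid$origin_y - 0.5 * grid$pixel_size),
      c(x0, grid$origin_y - (nr - 0.5) * grid$pixel_size))), crs = grid$crs)
  } else feature_set("line", crs = grid$crs)

  ## population: log-normal noise over a blurred urban/settlement kernel
  seed_mask <- (lulc == codes[["urban"]]) * 1
  if (!is.null(settle_xy)) {
    cc2 <- coords_to_cell(grid, settle_xy[, 1], settle_xy[, 2])
    ok <- !is.na(cc2$row)
    seed_mask[cbind(cc2$row[ok], cc2$col[ok])] <-
      pmax(seed_mask[cbind(cc2$row[ok], cc2$col[ok])], 0.6)
  }
  kern <- as.matrix(EBImage::gblur(seed_mask, sigma = min(6, (nr - 3) / 7)))
  kern[kern < 1e-4] <- 0   # filter ringing can leave tiny negatives
  pop <- kern / max(max(kern), 1e-12) *
    matrix(stats::rlnorm(n, sdlog = 0.6), nr, nc)
  pop <- pop / max(max(pop), 1e-12) * params$pop_max
  pop[pop < 0.01] <- 0

  ## radiance: blurred scaled population + flares at the first wells
  rad <- pmax(as.matrix(EBImage::gblur(pop, sigma = min(3, (nr - 3) / 7))), 0)
  rad <- rad / max(max(rad), 1e-12) * params$radiance_max

  infra <- draw_infrastructure(lulc, grid, params)
  if (params$n_wells > 0 && n_features(infra$wells) > 0) {
    nflare <- min(2, n_features(infra$wells))
    for (i in seq_len(nflare)) {
      p <- infra$wells$geom[[i]]
      cc3 <- coords_to_cell(grid, p[1], p[2])
      if (!is.na(cc3$row)) rad[cc3$row, cc3$col] <- params$flare_radiance
    }
  }

  structure(list(
    grid = grid,
    elevation = raster_layer(elevation, grid),
    slope = raster_layer(slope, grid),
    lulc = lulc_r,
    population = raster_layer(pop, grid),
    radiance = raster_layer(rad, grid),
    water = raster_layer((lulc == codes[["water"]]) * 1, grid),
    features = c(list(settlements = settlements, roads = roads,
                      trails = trails, railway = railway,
                      waterways = waterways, coastline = coast),
                 infra),
    params = params, seed = seed), class = "hf_landscape")
}

#' @export
print.hf_landscape <- function(x, ...) {
  cat(sprintf("<hf_landscape> %s, seed %d, %d settlements, %d road edges\n",
              format(x$grid), x$seed, n_features(x$features$settlements),
              n_features(x$features$roads)))
  invisible(x)
}

# rank-based class assignment: exact target counts, ordered by field value
assign_by_rank <- function(field, fractions, class_codes) {
  m <- length(field)
  counts <- round(fractions / sum(fractions) * m)
  counts[length(counts)] <- m - sum(counts[-length(counts)])
  out <- numeric(m)
  rk <- rank(-field, ties.method = "first")  # 1 = highest field value
  upper <- cumsum(counts)
  lower <- c(0, upper[-length(upper)])
  for (i in seq_along(class_codes))
    out[rk > lower[i] & rk <= upper[i]] <- class_codes[i]
  out
}

slope_percent <- function(elev, pixel_size) {
  nr <- nrow(elev); nc <- ncol(elev)
  pad_c <- elev[, c(1, seq_len(nc), nc)]
  pad_r <- elev[c(1, seq_len(nr), nr), ]
  gx <- (pad_c[, seq_len(nc) + 2] - pad_c[, seq_len(nc)]) / (2 * pixel_size)
  gy <- (pad_r[seq_len(nr) + 2, ] - pad_r[seq_len(nr), ]) / (2 * pixel_size)
  100 * sqrt(gx^2 + gy^2)
}

# Prim-style spanning tree over settlement points; edge class by length
build_road_network <- function(xy, grid) {
  if (is.null(xy) || nrow(xy) < 2)
    return(feature_set("line", crs = grid$crs,
                       data = data.frame(road_class = integer())))
  k <- nrow(xy)
  in_tree <- c(TRUE, rep(FALSE, k - 1))
  edges <- list()
  dmat <- as.matrix(stats::dist(xy))
  while (!all(in_tree)) {
    sub <- dmat[in_tree, !in_tree, drop = FALSE]
    idx <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    from <- which(in_tree)[idx[1]]
    to <- which(!in_tree)[idx[2]]
    edges[[length(edges) + 1]] <- c(from, to)
    in_tree[to] <- TRUE
  }
  lens <- purrr::map_dbl(edges, function(e) dmat[e[1], e[2]])
  ord <- rank(-lens, ties.method = "first")
  cls <- ifelse(ord <= ceiling(length(edges) / 4), 1L,
                ifelse(ord <= ceiling(length(edges) / 2), 2L, 3L))
  geoms <- purrr::map(edges, function(e) {
    mid <- (xy[e[1], ] + xy[e[2], ]) / 2 +
      stats::rnorm(2, sd = 5 * grid$pixel_size)
    rbind(xy[e[1], ], mid, xy[e[2], ])
  })
  feature_set("line", geoms, data = data.frame(road_class = cls),
              crs = grid$crs)
}

build_trails <- function(xy, grid, n_trails) {
  if (is.null(xy) || n_trails == 0 || nrow(xy) == 0)
    return(feature_set("line", crs = grid$crs))
  starts <- xy[sample(nrow(xy), n_trails, replace = TRUE), , drop = FALSE]
  geoms <- purrr::map(seq_len(n_trails), function(i) {
    ang <- stats::runif(1, 0, 2 * pi)
    len <- stats::runif(1, 20, 60) * grid$pixel_size
    rbind(starts[i, ], starts[i, ] + len * c(cos(ang), sin(ang)))
  })
  feature_set("line", geoms, crs = grid$crs)
}

build_railway <- function(xy, grid) {
  if (is.null(xy) || nrow(xy) < 2) return(feature_set("line", crs = grid$crs))
  dmat <- as.matrix(stats::dist(xy))
  idx <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
  feature_set("line", list(rbind(xy[idx[1], ], xy[idx[2], ])),
              crs = grid$crs)
}

build_waterways <- function(elev, grid, n_rivers = 3) {
  nr <- nrow(elev); nc <- ncol(elev)
  cc <- pixel_centers(grid)
  tops <- order(-as.vector(elev))[seq_len(n_rivers) * 97]
  geoms <- purrr::map(tops, function(k) {
    r <- ((k - 1) %% nr) + 1; c <- ((k - 1) %/% nr) + 1
    path <- matrix(c(cc$x[c], cc$y[r]), ncol = 2)
    for (step in seq_len(4 * (nr + nc))) {
      ri <- max(1, r - 1):min(nr, r + 1)
      ci <- max(1, c - 1):min(nc, c + 1)
      sub <- elev[ri, ci, drop = FALSE]
      m <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      nr2 <- ri[m[1]]; nc2 <- ci[m[2]]
      if (elev[nr2, nc2] >= elev[r, c]) break
      r <- nr2; c <- nc2
      path <- rbind(path, c(cc$x[c], cc$y[r]))
    }
    path
  })
  geoms <- geoms[purrr::map_int(geoms, nrow) >= 2]
  feature_set("line", geoms, crs = grid$crs)
}

draw_infrastructure <- function(lulc, grid, params) {
  codes <- hf_lulc_codes()
  nr <- nrow(lulc); nc <- ncol(lulc)
  cc <- pixel_centers(grid)
  rand_points <- function(k, cells) {
    if (k == 0 || !length(cells)) return(feature_set("point", crs = grid$crs))
    draw <- sample(cells, min(k, length(cells)))
    r <- ((draw - 1) %% nr) + 1; c <- ((draw - 1) %/% nr) + 1
    feature_set("point",
                purrr::map(seq_along(draw), function(i) c(cc$x[c[i]],
                                                          cc$y[r[i]])),
                crs = grid$crs)
  }
  land <- which(!(lulc %in% codes[c("water", "urban")]))
  human <- which(lulc %in% codes[c("agriculture", "pasture")])
  list(wells = rand_points(params$n_wells, land),
       refineries = rand_points(params$n_refineries, human),
       filling_stations = rand_points(params$n_filling, human),
       mines = rand_points(params$n_mines, land),
       power_points = rand_points(params$n_power, human))
}
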