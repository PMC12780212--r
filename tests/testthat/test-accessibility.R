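test_that("walking speed formulas match closed-form evaluation", {
  expect_equal(speed_walk_agriculture(1), 10.560326)
  expect_equal(speed_walk_agriculture(4), 10.560326 * 4^-0.199553)
  expect_equal(speed_walk_agriculture(4), 8.008191, tolerance = 1e-6)
  expect_equal(speed_walk_agriculture(0.2), 10.560326)  # slope clamp at 1 %
  expect_equal(speed_walk_natural(1), 6.761258)
  expect_equal(speed_walk_natural(1, flooded = TRUE), 3.380629)
  expect_equal(speed_walk_natural(10), -0.975931 * log(10) + 6.761258)
  expect_equal(speed_walk_natural(10), 4.514094, tolerance = 1e-6)
  # the log law goes negative on extreme slopes: floored, never <= 0
  expect_equal(speed_walk_natural(5000), 0.1)
})

test_that("waterway speeds reproduce the full slope x elevation matrix", {
  slopes <- c(2, 7, 12, 20, 30)       # one per slope band
  elevs <- c(300, 500, 1000, 2000, 3000)  # one per elevation band
  printed <- rbind(
    c(15,  7.5, 3.8, 1.9, 1.4),
    c(7.5, 3.9, 2.7, 1.9, 1.4),
    c(3.8, 2.7, 2.0, 1.7, 1.4),
    c(1.9, 1.9, 1.7, 1.4, 1.3),
    c(1.4, 1.4, 1.4, 1.3, 1.2))
  for (ei in 1:5) for (si in 1:5)
    expect_equal(speed_waterway(slopes[si], elevs[ei]), printed[ei, si])
  # band edges: 5 % falls in the 5-10 band, 450 m in the 450-700 band
  expect_equal(speed_waterway(5, 300), 7.5)
  expect_equal(speed_waterway(2, 450), 7.5)
})

test_that("the speed surface honours precedence and matches a per-pixel oracle", {
  set.seed(14)
  n <- 25
  g <- grid_spec(n, n)
  lulc <- matrix(sample(1:8, n * n, TRUE), n, n)
  slope <- matrix(runif(n * n, 0, 40), n, n)
  elev <- matrix(runif(n * n, 0, 3500), n, n)
  roads <- matrix(sample(0:3, n * n, TRUE, prob = c(0.7, 0.1, 0.1, 0.1)),
                  n, n)
  ww <- matrix(rbinom(n * n, 1, 0.2), n, n)
  coast <- matrix(rbinom(n * n, 1, 0.1), n, n)
  sp <- build_speed_surface(
    raster_layer(lulc, g, kind = "categorical"), raster_layer(slope, g),
    raster_layer(elev, g), roads = raster_layer(roads, g, "categorical"),
    waterways = raster_layer(ww, g), coastline = raster_layer(coast, g))
  for (k in sample(n * n, 120)) {
    expect_equal(sp[k], oracle_speed(lulc[k], slope[k], elev[k], roads[k],
                                     ww[k], coast[k]))
  }
  # a pixel with both a primary road and a waterway moves at road speed
  stopifnot(any(roads == 1 & ww == 1))
  expect_true(all(sp[roads == 1 & ww == 1] == 60))
})

test_that("pixel crossing time is pixel length over speed", {
  g <- grid_spec(3, 3, pixel_size = 30)
  sp <- raster_layer(matrix(c(60, 15, 1, 30, 40, 20, 5, 10, 2), 3, 3), g)
  ct <- pixel_crossing_time(sp)
  expect_equal(ct[1, 1], 0.0005)  # 1.8 seconds at 60 km/h
  expect_equal(ct[2, 1], 0.002)
  expect_equal(unclass(ct), 0.03 / unclass(sp), ignore_attr = TRUE)
  expect_error(pixel_crossing_time(raster_layer(0, g)), "positive")
})

test_that("source extraction keeps clusters of two or more pixels", {
  g <- grid_spec(10, 10)
  lone <- matrix(0, 10, 10); lone[5, 5] <- 1
  expect_error(extract_sources(raster_layer(lone, g)), "no accessibility|minimum size")
  pair <- lone; pair[6, 6] <- 1  # diagonal pair: 8-connected cluster of 2
  src <- extract_sources(raster_layer(pair, g))
  expect_equal(sum(src != 0), 2)
  mixed <- matrix(0, 10, 10)
  mixed[1, 1] <- 1                       # singleton: dropped
  mixed[3, 3:5] <- 1                     # cluster of 3: kept
  mixed[8:9, 8] <- 1                     # cluster of 2: kept
  src2 <- extract_sources(raster_layer(mixed, g))
  expect_equal(sum(src2 != 0), 5)
  expect_equal(src2[1, 1], 0)
})

test_that("least-cost time equals the igraph shortest-path oracle", {
  skip_if_not_installed("igraph")
  g <- grid_spec(20, 20)
  set.seed(77)
  for (rep in 1:3) {
    cost <- matrix(runif(400, 0.001, 0.05), 20, 20)
    src <- random_mask(20, 20, 0.03)
    got <- least_cost_time(raster_layer(cost, g), raster_layer(src, g))
    expect_equal(got$hours, igraph_travel_time(cost, src),
                 tolerance = 1e-12)
  }
})

test_that("uniform cost fields accumulate k*c per rook step", {
  g <- grid_spec(9, 9)
  cost <- raster_layer(matrix(0.002, 9, 9), g)
  src <- matrix(0, 9, 9); src[1, 1] <- 1
  tt <- least_cost_time(cost, raster_layer(src, g))
  expect_equal(tt$hours[1, 6], 5 * 0.002)
  expect_equal(tt$hours[9, 9], 16 * 0.002)
  expect_equal(tt$hours[1, 1], 0)
})

test_that("a fast corridor never increases any travel time", {
  g <- grid_spec(30, 30)
  set.seed(5)
  cost <- matrix(runif(900, 0.01, 0.05), 30, 30)
  src <- matrix(0, 30, 30); src[15, 1] <- 1
  base <- least_cost_time(raster_layer(cost, g), raster_layer(src, g))
  road <- cost; road[15, ] <- 1e-6
  faster <- least_cost_time(raster_layer(road, g), raster_layer(src, g))
  expect_true(all(faster$hours <= base$hours + 1e-12))
})

test_that("travel time satisfies the relaxation property", {
  g <- grid_spec(15, 15)
  set.seed(31)
  cost <- matrix(runif(225, 0.001, 0.1), 15, 15)
  src <- random_mask(15, 15, 0.05)
  tt <- least_cost_time(raster_layer(cost, g), raster_layer(src, g))$hours
  cc <- cost; cc[src != 0] <- cost[src != 0]
  for (i in 1:15) for (j in 1:14) {
    step <- (cost[i, j] + cost[i, j + 1]) / 2
    expect_lte(tt[i, j], tt[i, j + 1] + step + 1e-12)
    expect_lte(tt[i, j + 1], tt[i, j] + step + 1e-12)
  }
})

test_that("barriers block propagation and isolated pixels come back Inf", {
  g <- grid_spec(5, 5)
  cost <- matrix(0.01, 5, 5)
  cost[, 3] <- NA  # a wall of barrier pixels
  src <- matrix(0, 5, 5); src[3, 1] <- 1
  tt <- least_cost_time(raster_layer(cost, g), raster_layer(src, g))
  expect_true(all(is.finite(tt$hours[, 1:2])))
  expect_true(all(!is.finite(tt$hours[, 3:5])))
})

test_that("tiling reproduces the untiled result and never underestimates", {
  g <- grid_spec(40, 40)
  set.seed(19)
  cost <- raster_layer(matrix(runif(1600, 0.001, 0.05), 40, 40), g)
  src <- raster_layer(random_mask(40, 40, 0.02), g)
  untiled <- least_cost_time(cost, src)
  one_tile <- tiled_least_cost(cost, src, n_tiles = c(1, 1),
                               overlap_m = 30)
  expect_equal(one_tile$hours, untiled$hours)
  full <- tiled_least_cost(cost, src, n_tiles = c(2, 2),
                           overlap_m = 40 * 30)  # overlap spans the grid
  expect_equal(full$hours, untiled$hours)
  small <- tiled_least_cost(cost, src, n_tiles = c(2, 2), overlap_m = 90)
  expect_true(all(small$hours >= untiled$hours - 1e-12))
  expect_error(tiled_least_cost(cost, src, overlap_m = 10), "minimum")
})

test_that("indirect scoring decays from 4 to zero over the 4-hour horizon", {
  g <- grid_spec(5, 5)
  hours <- matrix(c(0, 1, 2, 4, 5, rep(3, 20)), 5, 5)
  hours[2, 2] <- Inf
  tt <- structure(list(grid = g, hours = hours,
                       sources = hours == 0), class = "hf_traveltime")
  s <- score_indirect(tt)
  expect_equal(s[1, 1], 4)                       # at the source
  expect_equal(s[3, 1], 4 * exp(-2 * log(40) / 4))
  expect_equal(s[3, 1], 0.6324555, tolerance = 1e-6)
  expect_equal(s[4, 1], 0.1)                     # the floor at 4 h
  expect_equal(s[5, 1], 0)                       # beyond the horizon
  expect_equal(s[2, 2], 0)                       # unreachable
  expect_true(all(s >= 0 & s <= 4))
})
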