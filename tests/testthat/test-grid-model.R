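test_that("grid and raster constructors enforce their invariants", {
  expect_error(grid_spec(0, 10), "n_rows")
  expect_error(grid_spec(10, 10, pixel_size = -1), "pixel_size")
  g <- grid_spec(10, 20, pixel_size = 30, origin_x = 100, origin_y = 700)
  cc <- pixel_centers(g)
  expect_equal(cc$x[1], 115)
  expect_equal(cc$y[1], 685)
  expect_equal(diff(cc$y)[1], -30)
  expect_error(raster_layer(matrix(0, 5, 5), g), "matrix matching")
  expect_error(raster_layer(matrix(1.5, 10, 20), g, kind = "categorical"),
               "integer category")
})

test_that("rasterize burns axis-aligned polygons by center containment", {
  g <- grid_spec(10, 10, pixel_size = 30)
  sq <- feature_set("polygon", list(rbind(c(30, 30), c(120, 30),
                                          c(120, 120), c(30, 120))))
  r <- rasterize(sq, g, burn = 10)
  expect_equal(sum(r == 10), 9)
  expect_equal(sum(r != 0), 9)
})

test_that("rasterize of an empty feature set yields an all-zero raster", {
  g <- grid_spec(8, 8)
  r <- rasterize(feature_set("point"), g, burn = 5)
  expect_true(all(r == 0))
})

test_that("overlapping polygons resolve by pixelwise maximum", {
  g <- grid_spec(12, 12, pixel_size = 30)
  polys <- feature_set("polygon", list(
    rbind(c(0, 0), c(180, 0), c(180, 180), c(0, 180)),
    rbind(c(90, 90), c(270, 90), c(270, 270), c(90, 270))),
    data = data.frame(score = c(5, 7)))
  r <- rasterize(polys, g, burn = "score")
  # per-pixel max oracle from two single-feature rasterizations
  r5 <- rasterize(polys[1, ] |> structure(kind = "polygon",
                                          crs = "local-metric",
                                          class = class(polys)), g, burn = 5)
  r7 <- rasterize(polys[2, ] |> structure(kind = "polygon",
                                          crs = "local-metric",
                                          class = class(polys)), g, burn = 7)
  expect_equal(unclass(r), pmax(unclass(r5), unclass(r7)),
               ignore_attr = TRUE)
  expect_true(all(r[unclass(r5) > 0 & unclass(r7) > 0] == 7))
})

test_that("rasterize burn-by-max is invariant to feature order and idempotent", {
  g <- grid_spec(15, 15, pixel_size = 30)
  set.seed(11)
  geoms <- purrr::map(1:6, function(i) {
    x0 <- runif(1, 0, 300); y0 <- runif(1, 0, 300)
    w <- runif(1, 60, 150); h <- runif(1, 60, 150)
    rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + h), c(x0, y0 + h))
  })
  scores <- c(2, 9, 4, 7, 5, 3)
  fwd <- rasterize(feature_set("polygon", geoms,
                               data.frame(s = scores)), g, burn = "s")
  ord <- c(4, 1, 6, 2, 5, 3)
  rev <- rasterize(feature_set("polygon", geoms[ord],
                               data.frame(s = scores[ord])), g, burn = "s")
  expect_equal(unclass(fwd), unclass(rev), ignore_attr = TRUE)
})

test_that("line rasterization touches every crossed pixel", {
  g <- grid_spec(10, 10, pixel_size = 30)
  # horizontal line through row of centers: touches 10 pixels
  horiz <- feature_set("line", list(rbind(c(0, 135), c(300, 135))))
  expect_equal(sum(rasterize(horiz, g, burn = 1) != 0), 10)
  # main diagonal of a 10x10 grid crosses 10 + 9 boundary-adjacent cells
  diag <- feature_set("line", list(rbind(c(1, 299), c(299, 1))))
  r <- rasterize(diag, g, burn = 1)
  expect_gte(sum(r != 0), 10)
  # every pixel containing a sampled point of the segment must be burned
  t <- seq(0, 1, length.out = 500)
  xs <- 1 + t * 298; ys <- 299 - t * 298
  rows <- floor((300 - ys) / 30) + 1; cols <- floor(xs / 30) + 1
  expect_true(all(r[cbind(rows, cols)] != 0))
})

test_that("rasterize rejects CRS mismatch and missing burn attribute", {
  g <- grid_spec(5, 5)
  pts <- feature_set("point", list(c(10, 10)), crs = "other-crs")
  expect_error(rasterize(pts, g, burn = 1), "CRS")
  pts2 <- feature_set("point", list(c(10, 10)))
  expect_error(rasterize(pts2, g, burn = "missing_col"), "missing_col")
})

test_that("bilinear resampling is exact for constants and source centers", {
  g <- grid_spec(10, 10, pixel_size = 30)
  const <- raster_layer(3.5, g)
  fine <- grid_spec(20, 20, pixel_size = 15, origin_x = 0, origin_y = 300)
  expect_true(all(resample(const, fine) == 3.5))
  # a linear ramp interpolates exactly everywhere
  cc <- pixel_centers(g)
  ramp <- raster_layer(outer(cc$y, cc$x, function(y, x) 2 * x + 0.5 * y), g)
  same <- resample(ramp, g)
  expect_equal(unclass(same), unclass(ramp), ignore_attr = TRUE)
  cc_f <- pixel_centers(fine)
  expected <- outer(cc_f$y, cc_f$x, function(y, x) 2 * x + 0.5 * y)
  inner <- 2:19  # interior pixels: no edge clamping
  got <- resample(ramp, fine)
  expect_equal(unclass(got)[inner, inner], expected[inner, inner],
               ignore_attr = TRUE)
})

test_that("categorical resampling takes the mode and invents no codes", {
  g <- grid_spec(2, 2, pixel_size = 30)
  r <- raster_layer(matrix(c(1, 1, 1, 2), 2, 2), g, kind = "categorical")
  coarse <- grid_spec(1, 1, pixel_size = 60, origin_x = 0, origin_y = 60)
  expect_equal(as.numeric(resample(r, coarse)), 1)
  g2 <- grid_spec(10, 10, pixel_size = 30)
  set.seed(5)
  cat10 <- raster_layer(matrix(sample(c(2, 7, 9), 100, TRUE), 10, 10), g2,
                        kind = "categorical")
  out <- resample(cat10, grid_spec(4, 4, pixel_size = 75, origin_y = 300))
  expect_true(all(unclass(out) %in% c(2, 7, 9)))
  expect_error(resample(structure(cat10, kind = "nonsense"), g2), "kind")
})

test_that("euclidean distance matches the brute-force oracle", {
  g <- grid_spec(20, 20, pixel_size = 30)
  m <- matrix(0, 20, 20); m[5, 5] <- 1
  d <- euclidean_distance(raster_layer(m, g))
  expect_equal(d[5, 5], 0)
  expect_equal(d[5, 8], 90)      # 3 columns away on a 30 m grid
  set.seed(21)
  for (rep in 1:3) {
    mm <- random_mask(20, 20, 0.05)
    dd <- euclidean_distance(raster_layer(mm, g))
    expect_equal(unclass(dd), brute_force_distance(mm, 30),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  expect_error(euclidean_distance(raster_layer(0, g)), "no on-pixels")
})

test_that("connected clusters match the flood-fill oracle", {
  g <- grid_spec(10, 10)
  single <- matrix(0, 10, 10); single[4, 7] <- 1
  cl <- connected_clusters(raster_layer(single, g), 4)
  expect_equal(cl$sizes$n_pixels, 1L)
  diag2 <- matrix(0, 10, 10); diag2[3, 3] <- 1; diag2[4, 4] <- 1
  expect_equal(connected_clusters(raster_layer(diag2, g), 8)$sizes$n_pixels,
               2L)
  expect_equal(nrow(connected_clusters(raster_layer(diag2, g), 4)$sizes), 2L)
  set.seed(33)
  for (conn in c(4, 8)) {
    mm <- random_mask(15, 15, 0.3)
    got <- sort(connected_clusters(raster_layer(mm, g15 <- grid_spec(15, 15)),
                                   conn)$sizes$n_pixels)
    expect_equal(got, flood_fill_sizes(mm, conn))
  }
})

test_that("water masking turns water pixels to NA and leaves the rest", {
  g <- grid_spec(8, 8)
  r <- raster_layer(matrix(runif(64), 8, 8), g)
  all_water <- raster_layer(1, g)
  expect_true(all(is.na(mask_water(r, all_water))))
  none <- raster_layer(0, g)
  expect_equal(unclass(mask_water(r, none)), unclass(r), ignore_attr = TRUE)
  checker <- raster_layer(matrix(rep(c(1, 0), 32), 8, 8), g)
  expect_equal(sum(is.na(mask_water(r, checker))), 32)
  g2 <- grid_spec(8, 8, origin_x = 999)
  expect_error(mask_water(r, raster_layer(0, g2)), "share one grid")
})

test_that("rasters and features survive a plain-text round trip", {
  withr::local_dir(withr::local_tempdir())
  g <- grid_spec(6, 7, pixel_size = 30, origin_x = 120, origin_y = 900)
  m <- matrix(round(runif(42), 3), 6, 7)
  m[2, 3] <- NA
  r <- raster_layer(m, g)
  write_ascii_grid(r, "r.asc")
  back <- read_ascii_grid("r.asc")
  expect_equal(unclass(back), unclass(r), ignore_attr = TRUE)
  expect_equal(attr(back, "grid")$origin_y, 900)
  lines <- feature_set("line", list(rbind(c(0, 0), c(90, 120)),
                                    rbind(c(30, 30), c(60, 60), c(90, 30))),
                       data = data.frame(road_class = c(1L, 3L)))
  write_features_csv(lines, "l.csv")
  back_l <- read_features_csv("l.csv", "line")
  expect_equal(back_l$road_class, c(1L, 3L))
  expect_equal(back_l$geom, lines$geom)
})
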