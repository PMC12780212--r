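test_that("stratification uses the 4/8/18 breaks with a closed top stratum", {
  g <- grid_spec(1, 6)
  r <- raster_layer(matrix(c(0, 3.9, 4, 7.9, 8, 18), 1, 6), g)
  s <- stratify(r)
  expect_equal(as.numeric(s), c(1, 1, 2, 2, 3, 4))
  expect_equal(validation_strata()$label,
               c("very_low", "low", "medium", "high"))
  expect_error(stratify(raster_layer(-0.1, g)), "nonnegative")
})

test_that("compromise allocation floors small strata and keeps the total", {
  eq <- allocate_samples(c(100, 100, 100, 100), 200, 0)
  expect_true(all(eq$n == 50))
  pure <- allocate_samples(c(700, 100, 100, 100), 100, 0)
  expect_equal(pure$n, c(70L, 10L, 10L, 10L))
  # one tiny stratum raised to the floor, paid for by the largest
  comp <- allocate_samples(c(9000, 500, 400, 100), 200, 15)
  expect_equal(sum(comp$n), 200)
  expect_true(all(comp$n >= 15))
  expect_lt(comp$n[1], floor(9000 / 10000 * 200) + 1)
  expect_error(allocate_samples(c(1, 1, 1, 1), 10, 5), "floor")
  set.seed(2)
  for (i in 1:10) {
    areas <- runif(4, 10, 1e4)
    al <- allocate_samples(areas, 300, 20)
    expect_equal(sum(al$n), 300)
    expect_true(all(al$n >= 20))
  }
})

test_that("plot draws are seeded, exact per stratum, and within strata", {
  ls <- small_landscape(5, 60)
  ds <- landscape_datasets(ls)
  hf <- build_hf(ds, ls$grid)
  strata <- stratify(hf$raster)
  areas <- as.numeric(table(factor(unclass(strata), levels = 1:4)))
  counts <- allocate_samples(areas, 60, 5)
  p1 <- draw_plots(strata, counts, seed = 99)
  p2 <- draw_plots(strata, counts, seed = 99)
  expect_identical(p1, p2)
  p3 <- draw_plots(strata, counts, seed = 100)
  expect_false(identical(p1, p3))
  drawn <- table(factor(p1$stratum, levels = 1:4))
  expect_equal(as.numeric(drawn), counts$n)
  # every plot lies in its claimed stratum
  expect_true(all(unclass(strata)[cbind(p1$row, p1$col)] == p1$stratum))
  expect_error(draw_plots(strata, c(1e6, 0, 0, 0), seed = 1), "pixels but")
})

test_that("visual score bands follow the coverage and occurrence rules", {
  expect_equal(visual_area_score(c(0, 0.05, 0.3, 0.6, 1)), c(0, 1, 2, 3, 3))
  expect_equal(visual_area_score(0.6), 3)   # >50 % coverage
  expect_equal(visual_line_score(c(0, 1, 2, 5)), c(0, 1, 2, 3))
})

test_that("visual standardization maps scores to the [0, 1] index", {
  mx <- default_pressure_maxima()
  mk <- function(score, pressure = "LU", kind = "area")
    tibble::tibble(plot_id = 1L, pressure = pressure, kind = kind,
                   score = score)
  expect_equal(standardize_visual(mk(0), mx)$visual_index, 0)
  # all pressures at the top band give exactly 1
  full <- purrr::map_dfr(names(mx), function(p)
    tibble::tibble(plot_id = 1L, pressure = p, kind = "area", score = 3))
  expect_equal(standardize_visual(full, mx)$visual_index, 1)
  # pasture at 40 % coverage: band 2 -> (2/3)*5.5 before normalization
  got <- standardize_visual(mk(visual_area_score(0.4)), mx)$visual_index
  expect_equal(got * sum(mx), 2 / 3 * 5.5)
  # within a pressure the maximum wins; indirect presence contributes 2
  two <- dplyr::bind_rows(mk(1), mk(3),
                          mk(1, pressure = "IND", kind = "indirect"))
  expect_equal(standardize_visual(two, mx)$visual_index * sum(mx),
               5.5 + 2)
  expect_error(standardize_visual(mk(4), mx), "out of range")
  expect_error(standardize_visual(mk(3, pressure = "QQ"), mx), "QQ")
})

test_that("tolerance kappa is 1 on agreement, negative on disagreement, ~0 on noise", {
  a <- runif(20)
  expect_equal(tolerance_kappa(a, a), 1)
  # alternating exact opposites: no observed agreement
  x <- rep(c(0, 1), 10); y <- rep(c(1, 0), 10)
  expect_lt(tolerance_kappa(x, y), 0)
  # hand-computed 2-point case: p_o = 0, p_e = 0.5 -> kappa = -1
  expect_equal(tolerance_kappa(c(0, 1), c(1, 0)), -1)
  set.seed(123)
  k <- tolerance_kappa(runif(1e4), runif(1e4))
  expect_lt(abs(k), 0.05)
  # constant vectors that agree within tolerance: kappa defined as 1
  expect_equal(tolerance_kappa(rep(0.4, 5), rep(0.4, 5)), 1)
  expect_equal(tolerance_kappa(rep(0.4, 5), rep(0.45, 5)), 1)
})

test_that("error metrics match hand-computed arithmetic", {
  a <- c(0.1, 0.4, 0.5, 0.8, 0.9)
  expect_equal(error_metrics(a, a)$rmse, 0)
  expect_equal(error_metrics(a, a)$r2, 1)
  shifted <- error_metrics(a, a + 0.1)
  expect_equal(shifted$rmse, 0.1)
  expect_equal(shifted$r2, 1)
  b <- c(0.2, 0.3, 0.6, 0.7, 1.0)
  m <- error_metrics(a, b)
  expect_equal(m$rmse, sqrt(sum((a - b)^2) / 5))
  expect_equal(m$r2, (sum((a - mean(a)) * (b - mean(b))) /
                        sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)))^2)
  expect_warning(z <- error_metrics(a, rep(0.5, 5)), "variance")
  expect_true(is.na(z$r2))
})

test_that("the full protocol recovers the map exactly from noiseless truth", {
  ls <- small_landscape(11, 80)
  ind <- landscape_indirect(ls)
  hf <- build_hf(landscape_datasets(ls), ls$grid, water = ls$water,
                 indirect = ind$indirect)
  strata <- stratify(hf$raster)
  areas <- as.numeric(table(factor(unclass(strata), levels = 1:4)))
  counts <- allocate_samples(areas, 80, 5)
  plots <- draw_plots(strata, counts, seed = 4)
  pr <- pressure_layers(hf)
  mx <- default_pressure_maxima()
  vt <- generate_visual_truth(plots, pr, mx, noise_sd = 0)
  v <- validate_hf(plots, pr, vt, mx)
  expect_equal(glance(v)$kappa, 1)
  expect_equal(glance(v)$rmse, 0)
  expect_equal(glance(v)$r2, 1)
  expect_equal(glance(v)$n_plots, 80)
  expect_named(tidy(v), c("plot_id", "hf_index", "visual_index", "stratum"))
})

test_that("uncertain plots are excluded from the metrics", {
  ls <- small_landscape(11, 60)
  hf <- build_hf(landscape_datasets(ls), ls$grid)
  strata <- stratify(hf$raster)
  areas <- as.numeric(table(factor(unclass(strata), levels = 1:4)))
  plots <- draw_plots(strata, allocate_samples(areas, 40, 4), seed = 2)
  plots$certain <- rep(c(TRUE, FALSE), 20)
  pr <- pressure_layers(hf)
  mx <- default_pressure_maxima()
  vt <- generate_visual_truth(plots, pr, mx, noise_sd = 0)
  v <- validate_hf(plots, pr, vt, mx)
  expect_equal(glance(v)$n_plots, 20)
})

test_that("metrics degrade monotonically on average as noise grows", {
  ls <- small_landscape(21, 80)
  hf <- build_hf(landscape_datasets(ls), ls$grid)
  strata <- stratify(hf$raster)
  areas <- as.numeric(table(factor(unclass(strata), levels = 1:4)))
  plots <- draw_plots(strata, allocate_samples(areas, 60, 5), seed = 8)
  pr <- pressure_layers(hf)
  mx <- default_pressure_maxima()
  levels <- c(0.2, 0.6, 1.2)
  means <- purrr::map_dfr(levels, function(sd) {
    per_seed <- purrr::map_dfr(1:6, function(s) {
      vt <- generate_visual_truth(plots, pr, mx, noise_sd = sd, seed = s)
      glance(validate_hf(plots, pr, vt, mx))
    })
    dplyr::summarise(per_seed, rmse = mean(rmse), kappa = mean(kappa))
  })
  expect_true(all(diff(means$rmse) > 0))
  expect_true(all(diff(means$kappa) < 0))
})
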