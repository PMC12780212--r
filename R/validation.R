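#' Stratify a reference human-influence raster
#'
#' Reclassifies a reference index (a global HF layer in the national
#' protocol, or the map under test on synthetic data) into four sampling
#' strata: very low (< 4), low (4-8), medium (8-18) and high (>= 18).
#'
#' @param reference Continuous nonnegative `hf_raster`.
#' @param breaks Stratum breakpoints (left-closed, right-open).
#' @return A categorical `hf_raster` with codes 1-4; see
#'   [validation_strata()].
#' @export
stratify <- function(reference, breaks = c(4, 8, 18)) {
  v <- raster_values(reference)
  if (any(v[!is.na(v)] < 0))
    stop("reference index must be nonnegative", call. = FALSE)
  s <- findInterval(v, breaks) + 1
  raster_like(matrix(as.numeric(s), nrow(v), ncol(v)), reference,
              kind = "categorical")
}

#' @rdname stratify
#' @return `validation_strata()` returns the stratum code/label tibble.
#' @export
validation_strata <- function() {
  tibble::tibble(stratum = 1:4,
                 label = c("very_low", "low", "medium", "high"))
}

#' Compromise sample allocation across strata
#'
#' Starts from an allocation proportional to stratum area, then raises
#' every stratum to a floor (small, high-pressure strata are otherwise
#' under-sampled), paying for the increase from the largest strata so the
#' total stays fixed — the compromise between user and producer/overall
#' accuracy used in map-accuracy assessment.
#'
#' @param strata_areas Named or unnamed numeric vector of stratum areas
#'   (pixel counts).
#' @param total_n Total number of plots.
#' @param min_per_stratum Floor per stratum (0 = pure proportional).
#' @return A tibble with `stratum`, `area`, `n`.
#' @export
allocate_samples <- function(strata_areas, total_n, min_per_stratum = 0) {
  k <- length(strata_areas)
  if (total_n < k * min_per_stratum)
    stop("total_n cannot honour the per-stratum floor", call. = FALSE)
  prop <- strata_areas / sum(strata_areas)
  n <- floor(prop * total_n)
  # distribute the rounding remainder to the largest fractional parts
  rem <- total_n - sum(n)
  if (rem > 0) {
    frac <- prop * total_n - n
    bump <- order(frac, decreasing = TRUE)[seq_len(rem)]
    n[bump] <- n[bump] + 1
  }
  # floor small strata, taking the difference from the currently largest
  while (any(n < min_per_stratum)) {
    i <- which(n < min_per_stratum)[1]
    need <- min_per_stratum - n[i]
    donors <- order(n, decreasing = TRUE)
    for (d in donors) {
      if (need == 0) break
      give <- min(need, n[d] - min_per_stratum)
      if (give <= 0) next
      n[d] <- n[d] - give
      need <- need - give
    }
    if (need > 0) stop("allocation infeasible under the floor", call. = FALSE)
    n[i] <- min_per_stratum
  }
  tibble::tibble(stratum = seq_len(k), area = as.numeric(strata_areas),
                 n = as.integer(n))
}

#' Draw stratified random validation plots
#'
#' Uniform sampling without replacement of pixels within each stratum.
#' Each drawn pixel center becomes the center of a square interpretation
#' plot with a circular context buffer around it.
#'
#' @param strata Categorical `hf_raster` from [stratify()].
#' @param counts Allocation tibble from [allocate_samples()] (or a numeric
#'   vector per stratum).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @param plot_size Plot edge length in meters (default 300).
#' @param buffer_radius Context buffer radius in meters (default 5000).
#' @return A tibble of plots: `plot_id`, `stratum`, `row`, `col`, `x`, `y`,
#'   `plot_size`, `buffer_radius`.
#' @export
draw_plots <- function(strata, counts, seed, plot_size = 300,
                       buffer_radius = 5000) {
  g <- attr(strata, "grid")
  if (is.data.frame(counts)) {
    n <- counts$n
    strata_ids <- counts$stratum
  } else {
    n <- counts
    strata_ids <- seq_along(counts)
  }
  sv <- raster_values(strata)
  cc <- pixel_centers(g)
  set.seed(seed)
  rows <- purrr::map2_dfr(strata_ids, n, function(s, ns) {
    cells <- which(!is.na(sv) & sv == s)
    if (length(cells) < ns)
      stop(sprintf("stratum %s has %d pixels but %d plots requested", s,
                   length(cells), ns), call. = FALSE)
    draw <- if (ns > 0) sample(cells, ns) else integer()
    tibble::tibble(stratum = s, cell = draw)
  })
  row <- ((rows$cell - 1) %% g$n_rows) + 1
  col <- ((rows$cell - 1) %/% g$n_rows) + 1
  tibble::tibble(plot_id = seq_len(nrow(rows)), stratum = rows$stratum,
                 row = row, col = col, x = cc$x[col], y = cc$y[row],
                 plot_size = plot_size, buffer_radius = buffer_radius)
}

#' Table 5-style visual scoring bands
#'
#' Banded visual scores used by photo interpreters: area pressures score by
#' plot coverage (0 %, up to 12 %, 13-50 %, over 50 % map to 0-3); line and
#' point pressures score by occurrences (0, 1, 2, more than 2 map to 0-3);
#' indirect pressure is a presence flag.
#'
#' @param coverage Fraction of the plot covered, in \[0, 1\].
#' @return Integer score 0-3.
#' @export
visual_area_score <- function(coverage) {
  stopifnot(all(coverage >= 0 & coverage <= 1))
  findInterval(coverage, c(0.005, 0.125, 0.5), left.open = TRUE)
}

#' @rdname visual_area_score
#' @param occurrences Count of line/point occurrences in the plot.
#' @export
visual_line_score <- function(occurrences) {
  stopifnot(all(occurrences >= 0))
  pmin(occurrences, 3L)
}

#' Standardize visual plot scores to a \[0, 1\] index
#'
#' Visual scores are standardized to the HF maxima of their pressures:
#' direct 0-3 scores become `(score / 3) * max_score`, indirect presence
#' becomes a fixed approximation value (2 by default); within each pressure
#' the standardized values combine by maximum, across pressures they sum,
#' and the sum is divided by the sum of per-pressure maxima so the index
#' lands in \[0, 1\].
#'
#' @param scores Long tibble with columns `plot_id`, `pressure`, `kind`
#'   (`"area"`, `"line"` or `"indirect"`) and `score` (0-3 for direct
#'   kinds, 0/1 for indirect; fractional values are allowed, supporting
#'   continuous synthetic truth).
#' @param max_scores Named numeric vector of per-pressure maxima (the
#'   normalization denominators), e.g. `c(BE = 10, LU = 5.5, ...)`.
#' @param indirect_value Standardized value of an indirect presence.
#' @return A tibble with `plot_id` and `visual_index`.
#' @export
standardize_visual <- function(scores, max_scores, indirect_value = 2) {
  stopifnot(all(c("plot_id", "pressure", "kind", "score") %in% names(scores)))
  if (any(scores$score < 0) ||
      any(scores$kind != "indirect" & scores$score > 3) ||
      any(scores$kind == "indirect" & scores$score > 1))
    stop("visual scores out of range (0-3 direct, 0-1 indirect)",
         call. = FALSE)
  unknown <- setdiff(unique(scores$pressure), names(max_scores))
  if (length(unknown))
    stop("no max score for pressure(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  denom <- sum(max_scores)
  scores |>
    dplyr::mutate(value = ifelse(.data$kind == "indirect",
                                 .data$score * indirect_value,
                                 .data$score / 3 *
                                   max_scores[.data$pressure])) |>
    dplyr::group_by(.data$plot_id, .data$pressure) |>
    dplyr::summarise(value = max(.data$value), .groups = "drop") |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::summarise(visual_index = sum(.data$value) / denom,
                     .groups = "drop")
}

#' Chance-corrected agreement with a tolerance (tolerance kappa)
#'
#' Cohen-style kappa for continuous paired scores on a common \[0, 1\]
#' scale: two scores "agree" when they differ by less than `tolerance`
#' (20 % of the scale by default). Observed agreement is the fraction of
#' agreeing pairs; chance agreement is the agreement rate over all ordered
#' cross-pairs of the two score vectors, which avoids binning the
#' continuous scores.
#'
#' @param a,b Numeric vectors in \[0, 1\], equal length >= 2.
#' @param tolerance Agreement tolerance on the normalized scale.
#' @return Kappa in \[-1, 1\].
#' @export
tolerance_kappa <- function(a, b, tolerance = 0.20) {
  stopifnot(length(a) == length(b), length(a) >= 2,
            all(a >= 0 & a <= 1), all(b >= 0 & b <= 1))
  p_o <- mean(abs(a - b) < tolerance)
  p_e <- mean(abs(outer(a, b, "-")) < tolerance)
  if (p_e >= 1) {
    if (p_o == 1) return(1)
    stop("chance agreement is 1 but observed is not; kappa undefined",
         call. = FALSE)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Paired error metrics
#'
#' Root mean squared error and the squared Pearson correlation (the share
#' of variance explained by a linear fit) of paired index values.
#'
#' @param a,b Numeric vectors, equal length >= 3.
#' @return A tibble with `rmse` and `r2` (`r2` is `NA` with a warning when
#'   either vector has zero variance).
#' @export
error_metrics <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  rmse <- sqrt(mean((a - b)^2))
  r2 <- if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in one score vector; r2 undefined", call. = FALSE)
    NA_real_
  } else stats::cor(a, b)^2
  tibble::tibble(rmse = rmse, r2 = r2)
}

#' Extract per-pressure values at validation plots
#'
#' @param pressures List of `hf_pressure` objects (or the output of
#'   [pressure_layers()]).
#' @param plots Plot tibble from [draw_plots()].
#' @param reduce `"center"` extracts the plot-center pixel; `"mean"`
#'   averages over the square plot window.
#' @return Long tibble with `plot_id`, `pressure`, `value`.
#' @export
extract_plot_pressures <- function(plots, pressures,
                                   reduce = c("center", "mean")) {
  reduce <- match.arg(reduce)
  purrr::map_dfr(pressures, function(p) {
    v <- raster_values(p$raster)
    g <- attr(p$raster, "grid")
    half <- floor(plots$plot_size / g$pixel_size / 2)
    val <- purrr::map2_dbl(plots$row, plots$col, function(r, c) {
      if (reduce == "center") return(v[r, c])
      ri <- max(1, r - half[1]):min(nrow(v), r + half[1])
      ci <- max(1, c - half[1]):min(ncol(v), c + half[1])
      mean(v[ri, ci], na.rm = TRUE)
    })
    tibble::tibble(plot_id = plots$plot_id, pressure = p$pressure_id,
                   value = val)
  })
}

#' Validate an HF map against visual plot scores
#'
#' Runs the technical-validation comparison: the map-side index at each
#' plot is the sum of the per-pressure layer values normalized by the sum
#' of per-pressure maxima; the visual side is standardized with
#' [standardize_visual()]; uncertain plots are excluded; and the agreement
#' is summarized with tolerance kappa, RMSE and R².
#'
#' @param plots Plot tibble from [draw_plots()], optionally with a logical
#'   `certain` column (uncertain plots are dropped from the metrics).
#' @param pressures List of `hf_pressure` layers of the map under test.
#' @param visual_scores Long visual-score tibble (see
#'   [standardize_visual()]).
#' @param max_scores Named per-pressure maxima used to normalize both
#'   sides.
#' @param tolerance Kappa agreement tolerance.
#' @param indirect_value Standardized value of an indirect presence.
#' @param reduce Plot extraction rule, see [extract_plot_pressures()].
#' @return An object of class `hf_validation` with the plot-level pairs and
#'   the metrics; see [tidy()] and [glance()].
#' @export
validate_hf <- function(plots, pressures, visual_scores, max_scores,
                        tolerance = 0.20, indirect_value = 2,
                        reduce = "center") {
  if ("certain" %in% names(plots)) plots <- plots[plots$certain, ]
  hf_side <- extract_plot_pressures(plots, pressures, reduce = reduce) |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::summarise(hf_index = sum(.data$value, na.rm = TRUE) /
                       sum(max_scores), .groups = "drop")
  vis_side <- standardize_visual(visual_scores[
    visual_scores$plot_id %in% plots$plot_id, ],
    max_scores, indirect_value = indirect_value)
  pairs <- dplyr::inner_join(hf_side, vis_side, by = "plot_id") |>
    dplyr::left_join(plots[c("plot_id", "stratum")], by = "plot_id")
  kappa <- tolerance_kappa(pairs$hf_index, pairs$visual_index,
                           tolerance = tolerance)
  em <- error_metrics(pairs$hf_index, pairs$visual_index)
  structure(list(plots = pairs,
                 metrics = tibble::tibble(kappa = kappa, rmse = em$rmse,
                                          r2 = em$r2, tolerance = tolerance,
                                          n_plots = nrow(pairs))),
            class = "hf_validation")
}

#' @export
print.hf_validation <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<hf_validation> %d plots  kappa %.3f (tol %.0f%%)  ",
                     "RMSE %.4f  R2 %.3f\n"),
              m$n_plots, m$kappa, 100 * m$tolerance, m$rmse, m$r2))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy plot-level validation pairs
#' @param x An `hf_validation`.
#' @param ... Unused.
#' @return Tibble of plot-level paired indices.
#' @method tidy hf_validation
#' @export
tidy.hf_validation <- function(x, ...) x$plots

#' One-row validation summary
#' @param x An `hf_validation`.
#' @param ... Unused.
#' @return One-row tibble with kappa, rmse, r2, tolerance, n_plots.
#' @method glance hf_validation
#' @export
glance.hf_validation <- function(x, ...) x$metrics
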