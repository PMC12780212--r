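#' Combine scored datasets into a pressure layer
#'
#' When several datasets describe one pressure (primary, secondary and
#' country roads within roads-and-railways, say) their scored rasters are
#' combined by the pixelwise maximum: the strongest mapped influence wins,
#' double counting within a pressure is avoided. `NA` is ignored unless
#' every input is `NA` at a pixel.
#'
#' @param scored List of continuous `hf_raster`s in \[0, 10\] on one grid
#'   (a single raster is also accepted).
#' @param pressure_id One of [hf_pressures()].
#' @param year Optional year tag.
#' @return An object of class `hf_pressure`.
#' @export
combine_pressure <- function(scored, pressure_id, year = NA_integer_) {
  if (inherits(scored, "hf_raster")) scored <- list(scored)
  if (!length(scored)) stop("no scored rasters supplied", call. = FALSE)
  if (!pressure_id %in% hf_pressures())
    stop("unknown pressure_id '", pressure_id, "'", call. = FALSE)
  g <- do.call(check_same_grid, c(scored, list(what = "scored rasters")))
  acc <- raster_values(scored[[1]])
  if (length(scored) > 1) {
    for (r in scored[-1]) {
      v <- raster_values(r)
      acc <- ifelse(is.na(acc), v, ifelse(is.na(v), acc, pmax(acc, v)))
    }
  }
  structure(list(pressure_id = pressure_id, year = year,
                 raster = raster_layer(acc, g, kind = "continuous")),
            class = "hf_pressure")
}

#' @export
print.hf_pressure <- function(x, ...) {
  cat(sprintf("<hf_pressure:%s>%s ", x$pressure_id,
              if (is.na(x$year)) "" else paste0(" year ", x$year)))
  print(x$raster)
  invisible(x)
}

#' Aggregate pressure layers into the HF index
#'
#' The HF index is the pixelwise sum of the pressure layers (one layer per
#' pressure, each in \[0, 10\]). Water pixels are masked to `NA` and values
#' are rounded half-even to 2 decimals, once, at the end. Missing values
#' within a single pressure count as 0 in the sum; a pixel that is `NA` in
#' every pressure stays `NA`.
#'
#' @param pressures List of `hf_pressure` objects with distinct
#'   `pressure_id`s.
#' @param water Optional binary water mask on the same grid.
#' @param year,version Tags carried on the result (`version` is the
#'   input-selection strategy: "SDG15", "Official" or "Multitemporal").
#' @return An object of class `hf_map`.
#' @export
aggregate_hf <- function(pressures, water = NULL, year = NA_integer_,
                         version = "SDG15") {
  stopifnot(length(pressures) >= 1,
            all(purrr::map_lgl(pressures, inherits, "hf_pressure")))
  ids <- purrr::map_chr(pressures, "pressure_id")
  if (anyDuplicated(ids))
    stop("duplicate pressure_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  rasters <- purrr::map(pressures, "raster")
  g <- do.call(check_same_grid, c(rasters, list(what = "pressure layers")))
  acc <- matrix(0, g$n_rows, g$n_cols)
  all_na <- matrix(TRUE, g$n_rows, g$n_cols)
  for (r in rasters) {
    v <- raster_values(r)
    all_na <- all_na & is.na(v)
    v[is.na(v)] <- 0
    acc <- acc + v
  }
  acc[all_na] <- NA_real_
  hf <- raster_layer(acc, g, kind = "continuous")
  if (!is.null(water)) hf <- mask_water(hf, water)
  hf <- raster_like(round(raster_values(hf), 2), hf)
  structure(list(raster = hf, year = year, version = version,
                 pressures = ids),
            class = "hf_map")
}

#' @export
print.hf_map <- function(x, ...) {
  cat(sprintf("<hf_map> version %s%s  pressures: %s\n", x$version,
              if (is.na(x$year)) "" else paste0(", year ", x$year),
              paste(x$pressures, collapse = "+")))
  print(x$raster)
  invisible(x)
}

#' Landscape classification of the HF index
#'
#' The generic four-class reading of the index: \[0, 1) original ecosystem
#' with no significant human influence; \[1, 4) original ecosystem with
#' human influence; \[4, 15) rural landscape (agriculture, pasture,
#' accessibility and indirect pressures); \[15, Inf) highly modified,
#' mostly urban landscape.
#'
#' @param hf An `hf_map` (or bare continuous `hf_raster`).
#' @param breaks Class breakpoints (left-closed, right-open).
#' @return A categorical `hf_raster` with codes 1-4; see [hf_classes()].
#' @export
classify_hf <- function(hf, breaks = c(1, 4, 15)) {
  r <- if (inherits(hf, "hf_map")) hf$raster else hf
  v <- raster_values(r)
  if (any(v[!is.na(v)] < 0))
    stop("HF index values must be nonnegative", call. = FALSE)
  cls <- findInterval(v, breaks) + 1
  raster_like(matrix(as.numeric(cls), nrow(v), ncol(v)), r,
              kind = "categorical")
}

#' @rdname classify_hf
#' @return `hf_classes()` returns the class code/label lookup tibble.
#' @export
hf_classes <- function() {
  tibble::tibble(
    class = 1:4,
    range = c("[0, 1)", "[1, 4)", "[4, 15)", "[15, Inf)"),
    label = c("original, no significant influence",
              "original with human influence",
              "rural landscape",
              "highly modified landscape"))
}

#' Score one configured dataset
#'
#' Dispatches a dataset entry (see [hf_dataset()]) to its scoring case and
#' returns the scored raster on `grid`.
#'
#' @param ds An [hf_dataset()].
#' @param grid Target [grid_spec()].
#' @param year Year whose data to use for multitemporal datasets.
#' @return A continuous `hf_raster` in \[0, 10\].
#' @export
score_dataset <- function(ds, grid, year = NA_integer_) {
  data <- dataset_data(ds, year)
  p <- ds$params
  scored <- switch(ds$case,
    direct = {
      if (inherits(data, "hf_features"))
        rasterize(data, grid, burn = p$score %||% 1)
      else score_direct(data, p$mapping)
    },
    decay = {
      mask <- if (inherits(data, "hf_features"))
        rasterize(data, grid, burn = 1) else data
      score_exponential_decay(euclidean_distance(mask),
                              s0 = p$s0 %||% 4,
                              max_dist = p$max_dist %||% 100,
                              floor = p$floor %||% 0.1)
    },
    log_count = score_log_count(data, coeff = p$coeff %||% 5.41,
                                cap_threshold = p$cap_threshold %||% 70),
    log_density = score_log_density(data, coeff = p$coeff %||% 2.5),
    linear = score_linear(data, vmin = p$vmin %||% 0.5,
                          vmax = p$vmax %||% 60, smax = p$smax %||% 10),
    point_actual = score_points(data, grid, score = p$score,
                                mode = "actual", radius = p$radius),
    point_approx = score_points(data, grid, score = p$score,
                                mode = "approx", s0 = p$s0 %||% 4,
                                max_dist = p$max_dist %||% 100,
                                floor = p$floor %||% 0.1),
    stop("unknown scoring case '", ds$case, "'", call. = FALSE))
  cap <- p$max_score %||% 10
  raster_like(pmin(raster_values(scored), cap), scored)
}

dataset_data <- function(ds, year) {
  if (!ds$multitemporal) return(ds$data)
  if (is.na(year) || is.null(ds$data[[as.character(year)]]))
    stop(sprintf("dataset '%s' has no data for year %s", ds$id, year),
         call. = FALSE)
  ds$data[[as.character(year)]]
}

#' Declare a dataset entry for an HF run
#'
#' @param id Dataset identifier.
#' @param pressure One of [hf_pressures()].
#' @param case Scoring case: `"direct"`, `"decay"`, `"log_count"`,
#'   `"log_density"`, `"linear"`, `"point_actual"` or `"point_approx"`.
#' @param data An `hf_raster` or [feature_set()]; for multitemporal
#'   datasets, a list of them named by year.
#' @param params Named list of case parameters (`score`, `mapping`,
#'   `radius`, `s0`, `max_dist`, `floor`, `coeff`, `cap_threshold`, `vmin`,
#'   `vmax`, `max_score`, ...).
#' @param multitemporal Whether `data` is a per-year list.
#' @param national Whether the dataset is nationally produced (drives the
#'   "Official" input-selection strategy).
#' @return An object of class `hf_dataset`.
#' @export
hf_dataset <- function(id, pressure, case, data, params = list(),
                       multitemporal = FALSE, national = TRUE) {
  if (!pressure %in% hf_pressures())
    stop(sprintf("dataset '%s': invalid pressure_id '%s'", id, pressure),
         call. = FALSE)
  check_case_params(id, case, params)
  structure(list(id = id, pressure = pressure, case = case, data = data,
                 params = params, multitemporal = multitemporal,
                 national = national),
            class = "hf_dataset")
}

check_case_params <- function(id, case, params) {
  need <- switch(case,
    direct = character(), decay = character(),
    log_count = character(), log_density = character(), linear = character(),
    point_actual = c("score", "radius"), point_approx = "score",
    stop(sprintf("dataset '%s': unknown scoring case '%s'", id, case),
         call. = FALSE))
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop(sprintf("dataset '%s' (%s case): missing param(s) %s", id, case,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Select datasets under an input-selection strategy
#'
#' "SDG15" is non-restrictive and keeps everything; "Official" keeps only
#' nationally produced datasets; "Multitemporal" keeps only datasets with
#' per-year updates.
#'
#' @param datasets List of [hf_dataset()] objects.
#' @param version One of `"SDG15"`, `"Official"`, `"Multitemporal"`.
#' @return Filtered list of datasets.
#' @export
filter_datasets <- function(datasets,
                            version = c("SDG15", "Official",
                                        "Multitemporal")) {
  version <- match.arg(version)
  keep <- switch(version,
    SDG15 = rep(TRUE, length(datasets)),
    Official = purrr::map_lgl(datasets, "national"),
    Multitemporal = purrr::map_lgl(datasets, "multitemporal"))
  datasets[keep]
}

#' Build one HF map from configured datasets
#'
#' Scores every dataset for the requested year, combines scored rasters by
#' pressure (max), adds the indirect-pressure layer if accessibility inputs
#' are supplied, aggregates pressures (sum), masks water and rounds. A
#' provenance table (dataset, pressure, case, parameters, year) is attached
#' as attribute `"provenance"`.
#'
#' @param datasets List of [hf_dataset()] objects.
#' @param grid Target [grid_spec()].
#' @param year Year to build.
#' @param version Input-selection strategy, see [filter_datasets()].
#' @param water Optional binary water mask.
#' @param indirect Optional precomputed indirect-pressure `hf_raster` (from
#'   [score_indirect()]).
#' @return An `hf_map`.
#' @export
build_hf <- function(datasets, grid, year = NA_integer_, version = "SDG15",
                     water = NULL, indirect = NULL) {
  datasets <- filter_datasets(datasets, version)
  if (!length(datasets)) stop("no datasets left after version filtering",
                              call. = FALSE)
  ids <- purrr::map_chr(datasets, "pressure")
  pressures <- purrr::map(unique(ids), function(pid) {
    scored <- purrr::map(datasets[ids == pid], score_dataset,
                         grid = grid, year = year)
    combine_pressure(scored, pid, year = year)
  })
  if (!is.null(indirect))
    pressures <- c(pressures, list(combine_pressure(indirect, "IND",
                                                    year = year)))
  hf <- aggregate_hf(pressures, water = water, year = year,
                     version = version)
  attr(hf, "provenance") <- tibble::tibble(
    dataset = purrr::map_chr(datasets, "id"),
    pressure = ids,
    case = purrr::map_chr(datasets, "case"),
    params = purrr::map_chr(datasets, function(d)
      paste(sprintf("%s=%s", names(d$params),
                    purrr::map_chr(d$params, function(x)
                      paste(format(unlist(x)), collapse = "/"))),
            collapse = "; ")),
    multitemporal = purrr::map_lgl(datasets, "multitemporal"),
    national = purrr::map_lgl(datasets, "national"),
    year = year, version = version)
  attr(hf, "pressure_layers") <- pressures
  hf
}

#' Provenance of a built HF map
#' @param hf An `hf_map` from [build_hf()].
#' @return The provenance tibble.
#' @export
provenance <- function(hf) attr(hf, "provenance")

#' Per-pressure layers of a built HF map
#' @param hf An `hf_map` from [build_hf()].
#' @return List of `hf_pressure` objects.
#' @export
pressure_layers <- function(hf) attr(hf, "pressure_layers")

#' Build a multi-year HF series
#'
#' Repeats scoring, combination and aggregation for each year; static
#' datasets are reused across years, multitemporal datasets must resolve
#' for every requested year (missing years are an error naming the
#' dataset).
#'
#' @inheritParams build_hf
#' @param years Integer vector of years.
#' @param indirect Optional named list (by year) of indirect-pressure
#'   rasters, or a single raster reused for all years.
#' @return Named list of `hf_map`s, one per year.
#' @export
build_series <- function(datasets, grid, years, version = "SDG15",
                         water = NULL, indirect = NULL) {
  sel <- filter_datasets(datasets, version)
  for (ds in sel) {
    if (ds$multitemporal) {
      missing <- setdiff(as.character(years), names(ds$data))
      if (length(missing))
        stop(sprintf("dataset '%s' lacks data for year(s) %s", ds$id,
                     paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  out <- purrr::map(years, function(y) {
    ind <- if (is.list(indirect) && !inherits(indirect, "hf_raster"))
      indirect[[as.character(y)]] else indirect
    build_hf(datasets, grid, year = y, version = version, water = water,
             indirect = ind)
  })
  names(out) <- as.character(years)
  out
}
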