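#' Load and validate a run configuration
#'
#' Reads a YAML run configuration describing the grid, the input-selection
#' version, the year list, the dataset entries (path, format, pressure,
#' scoring case and parameters, static/multitemporal and national/global
#' flags), accessibility parameters and validation parameters. All
#' referenced files are loaded eagerly (relative paths resolve against the
#' config file's directory); defaults are applied for omitted blocks;
#' unknown keys, missing files and invalid parameters are rejected with
#' the offending field path.
#'
#' @param path Path to a YAML config file.
#' @return An object of class `hf_config`: list with `grid`, `version`,
#'   `years`, `datasets` (a list of [hf_dataset()]), `water`,
#'   `accessibility`, `validation`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  base_dir <- dirname(normalizePath(path))
  known <- c("grid", "version", "years", "datasets", "water",
             "accessibility", "validation")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(raw$grid)) stop("config needs a `grid` block", call. = FALSE)
  g <- raw$grid
  grid <- grid_spec(g$n_rows, g$n_cols,
                    pixel_size = g$pixel_size %||% 30,
                    origin_x = g$origin_x %||% 0,
                    origin_y = g$origin_y %||% (g$n_rows *
                                                  (g$pixel_size %||% 30)),
                    crs = g$crs %||% "local-metric")
  version <- raw$version %||% "SDG15"
  if (!version %in% c("SDG15", "Official", "Multitemporal"))
    stop("version: must be SDG15, Official or Multitemporal", call. = FALSE)
  years <- as.integer(raw$years %||% NA_integer_)
  datasets <- purrr::imap(raw$datasets %||% list(), function(d, i)
    load_config_dataset(d, i, base_dir, grid$crs))
  water <- NULL
  if (!is.null(raw$water)) {
    wp <- resolve_path(raw$water$path, base_dir, "water.path")
    water <- read_ascii_grid(wp, kind = "continuous", crs = grid$crs)
  }
  acc <- apply_defaults(raw$accessibility %||% list(),
                        list(s0 = 4, t_max = 4, floor = 0.1, n_tiles = NULL,
                             overlap_m = 100e3), "accessibility")
  val <- apply_defaults(raw$validation %||% list(),
                        list(total_n = 200, min_per_stratum = 20,
                             tolerance = 0.2, seed = 1, plot_size = 300,
                             buffer_radius = 5000, indirect_value = 2),
                        "validation")
  structure(list(grid = grid, version = version, years = years,
                 datasets = datasets, water = water, accessibility = acc,
                 validation = val, raw = raw, base_dir = base_dir),
            class = "hf_config")
}

apply_defaults <- function(block, defaults, where) {
  bad <- setdiff(names(block), names(defaults))
  if (length(bad))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(bad, collapse = ", ")), call. = FALSE)
  utils::modifyList(defaults, block)
}

resolve_path <- function(p, base_dir, field) {
  if (is.null(p)) stop(field, ": missing path", call. = FALSE)
  full <- if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  if (!file.exists(full))
    stop(sprintf("%s: file not found (%s)", field, p), call. = FALSE)
  full
}

load_config_dataset <- function(d, i, base_dir, crs) {
  where <- sprintf("datasets[%d]", i)
  known <- c("id", "pressure", "case", "path", "paths", "format", "kind",
             "params", "multitemporal", "national")
  bad <- setdiff(names(d), known)
  if (length(bad))
    stop(sprintf("%s: unknown key(s) %s", where,
                 paste(bad, collapse = ", ")), call. = FALSE)
  id <- d$id %||% stop(where, ": missing id", call. = FALSE)
  if (is.null(d$pressure) || !d$pressure %in% hf_pressures())
    stop(sprintf("%s (%s): invalid pressure '%s'", where, id,
                 d$pressure %||% "<missing>"), call. = FALSE)
  fmt <- d$format %||% "ascii_grid"
  reader <- switch(fmt,
    ascii_grid = function(p) read_ascii_grid(p, kind = d$kind %||%
                                               "continuous", crs = crs),
    points_csv = function(p) read_features_csv(p, "point", crs = crs),
    lines_csv = function(p) read_features_csv(p, "line", crs = crs),
    polygons_csv = function(p) read_features_csv(p, "polygon", crs = crs),
    stop(sprintf("%s (%s): unknown format '%s'", where, id, fmt),
         call. = FALSE))
  multitemporal <- isTRUE(d$multitemporal)
  data <- if (multitemporal) {
    if (is.null(d$paths))
      stop(sprintf("%s (%s): multitemporal dataset needs `paths` by year",
                   where, id), call. = FALSE)
    purrr::imap(d$paths, function(p, y)
      reader(resolve_path(p, base_dir, sprintf("%s.paths.%s", where, y))))
  } else {
    reader(resolve_path(d$path, base_dir, paste0(where, ".path")))
  }
  params <- d$params %||% list()
  if (!is.null(params$mapping))
    params$mapping <- unlist(params$mapping)
  hf_dataset(id, d$pressure, d$case %||%
               stop(sprintf("%s (%s): missing case", where, id),
                    call. = FALSE),
             data, params = params, multitemporal = multitemporal,
             national = d$national %||% TRUE)
}

#' @export
print.hf_config <- function(x, ...) {
  cat(sprintf("<hf_config> version %s, year(s) %s, %d dataset(s), %s\n",
              x$version, paste(x$years, collapse = "/"), length(x$datasets),
              format(x$grid)))
  invisible(x)
}

#' Serialize a run configuration back to YAML
#'
#' Writes the normalized configuration (defaults applied) so that loading
#' the written file yields a semantically identical configuration.
#'
#' @param config An `hf_config`.
#' @param path Output YAML path; data files are referenced, not copied.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "hf_config"))
  raw <- config$raw
  raw$version <- config$version
  raw$accessibility <- config$accessibility[
    !purrr::map_lgl(config$accessibility, is.null)]
  raw$validation <- config$validation
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Run the HF pipeline from a configuration
#'
#' Builds the configured year series via [build_series()], including the
#' water mask from the config. Indirect pressure must be supplied
#' precomputed (see [landscape_indirect()]) or omitted.
#'
#' @param config An `hf_config` from [load_config()].
#' @param indirect Optional indirect-pressure raster or per-year list.
#' @return Named list of `hf_map`s, one per configured year.
#' @export
run_config <- function(config, indirect = NULL) {
  stopifnot(inherits(config, "hf_config"))
  build_series(config$datasets, config$grid, config$years,
               version = config$version, water = config$water,
               indirect = indirect)
}
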