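#' Define a projected raster grid
#'
#' A grid spec is the georeferencing contract shared by every layer in an HF
#' run: a projected, meter-unit coordinate system, a top-left map origin, a
#' square pixel size and the raster dimensions. Pixel centers sit at
#' `origin + (index - 0.5) * pixel_size`; rows count downward from the top
#' edge, columns rightward from the left edge.
#'
#' @param n_rows,n_cols Raster dimensions (positive integers).
#' @param pixel_size Pixel edge length in meters. Default 30, the working
#'   resolution of the national HF series.
#' @param origin_x,origin_y Map coordinates (m) of the top-left grid corner.
#' @param crs Identifier of the projected CRS. Informational: operations
#'   require that layers share this string, they never reproject on the fly.
#' @return An object of class `hf_grid`.
#' @examples
#' g <- grid_spec(100, 100)
#' g
#' @export
grid_spec <- function(n_rows, n_cols, pixel_size = 30,
                      origin_x = 0, origin_y = n_rows * pixel_size,
                      crs = "local-metric") {
  stopifnot(n_rows >= 1, n_cols >= 1, pixel_size > 0)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         pixel_size = as.numeric(pixel_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         crs = crs),
    class = "hf_grid"
  )
}

#' @export
print.hf_grid <- function(x, ...) {
  cat(sprintf("<hf_grid> %d x %d pixels @ %g m, origin (%g, %g), crs '%s'\n",
              x$n_rows, x$n_cols, x$pixel_size, x$origin_x, x$origin_y, x$crs))
  invisible(x)
}

#' @export
format.hf_grid <- function(x, ...) {
  sprintf("%dx%d@%gm", x$n_rows, x$n_cols, x$pixel_size)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a[c("n_rows", "n_cols", "pixel_size",
                       "origin_x", "origin_y")],
                   b[c("n_rows", "n_cols", "pixel_size",
                       "origin_x", "origin_y")])) &&
    identical(a$crs, b$crs)
}

check_same_grid <- function(..., what = "layers") {
  layers <- list(...)
  g <- layer_grid(layers[[1]])
  for (l in layers[-1]) {
    if (!grids_identical(g, layer_grid(l)))
      stop(sprintf("%s must share one grid (CRS, origin, pixel size, shape); ",
                   what),
           "reproject/resample inputs before combining them", call. = FALSE)
  }
  invisible(g)
}

layer_grid <- function(x) {
  if (inherits(x, "hf_raster")) attr(x, "grid") else x$grid
}

#' Pixel-center coordinates of a grid
#'
#' @param grid An [grid_spec()] object.
#' @return A list with `x` (length `n_cols`) and `y` (length `n_rows`,
#'   decreasing from the top row down) center coordinates in meters.
#' @export
pixel_centers <- function(grid) {
  list(x = grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$pixel_size,
       y = grid$origin_y - (seq_len(grid$n_rows) - 0.5) * grid$pixel_size)
}

# map coordinates -> (row, col); returns NA outside the grid
coords_to_cell <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$pixel_size) + 1
  row <- floor((grid$origin_y - y) / grid$pixel_size) + 1
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Construct a raster layer
#'
#' The in-memory raster container used throughout the package: a numeric
#' matrix (rows top to bottom) bound to a [grid_spec()]. Missing cells are
#' stored as `NA`; the `nodata` sentinel is only applied when writing to
#' disk.
#'
#' @param values Numeric matrix `n_rows x n_cols`, or a single number to
#'   fill the grid.
#' @param grid A [grid_spec()].
#' @param kind `"continuous"` or `"categorical"`. Categorical values must be
#'   integer codes.
#' @param nodata Sentinel written for `NA` cells on export. Defaults to
#'   -9999 (continuous) or 255 (categorical).
#' @return An object of class `hf_raster` (a matrix with attributes).
#' @examples
#' r <- raster_layer(0, grid_spec(10, 10))
#' @export
raster_layer <- function(values, grid, kind = c("continuous", "categorical"),
                         nodata = NULL) {
  kind <- match.arg(kind)
  if (length(values) == 1)
    values <- matrix(as.numeric(values), grid$n_rows, grid$n_cols)
  if (!is.matrix(values) ||
      nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop("`values` must be an n_rows x n_cols matrix matching the grid",
         call. = FALSE)
  if (kind == "categorical" &&
      any(values[!is.na(values)] != round(values[!is.na(values)])))
    stop("categorical rasters must hold integer category codes", call. = FALSE)
  if (is.null(nodata)) nodata <- if (kind == "continuous") -9999 else 255
  structure(values, grid = grid, kind = kind, nodata = nodata,
            class = c("hf_raster", "matrix", "array"))
}

# rebuild a raster from a bare matrix, inheriting metadata from a template
raster_like <- function(values, template, kind = NULL) {
  raster_layer(values, attr(template, "grid"),
               kind = kind %||% attr(template, "kind"))
}

raster_values <- function(x) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(y))
  y
}

#' @export
print.hf_raster <- function(x, ...) {
  g <- attr(x, "grid")
  v <- x[!is.na(x)]
  cat(sprintf("<hf_raster:%s> %s  range [%s, %s]  NA: %d\n",
              attr(x, "kind"), format(g),
              if (length(v)) signif(min(v), 5) else "-",
              if (length(v)) signif(max(v), 5) else "-",
              sum(is.na(x))))
  invisible(x)
}

#' Tidy a raster into a pixel table
#'
#' @param x An `hf_raster`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `x`, `y` (pixel-center map
#'   coordinates) and `value`.
#' @method as_tibble hf_raster
#' @export
as_tibble.hf_raster <- function(x, ...) {
  g <- attr(x, "grid")
  cc <- pixel_centers(g)
  tibble::tibble(
    row = rep(seq_len(g$n_rows), times = g$n_cols),
    col = rep(seq_len(g$n_cols), each = g$n_rows),
    x = rep(cc$x, each = g$n_rows),
    y = rep(cc$y, times = g$n_cols),
    value = as.vector(raster_values(x))
  )
}

#' Build a vector feature set
#'
#' Features are stored as a tibble with a `geom` list-column of two-column
#' `(x, y)` coordinate matrices, one matrix per feature (polygons are single
#' closed rings; multi-part geometries are separate features). Attribute
#' columns ride along and can be used as burn values in [rasterize()].
#'
#' @param kind `"point"`, `"line"` or `"polygon"`.
#' @param geoms List of numeric matrices with columns x, y (points may be
#'   length-2 vectors).
#' @param data Optional data frame of per-feature attributes.
#' @param crs CRS identifier; must match the grid CRS at rasterization.
#' @return A tibble of class `hf_features`.
#' @export
feature_set <- function(kind = c("point", "line", "polygon"),
                        geoms = list(), data = NULL, crs = "local-metric") {
  kind <- match.arg(kind)
  geoms <- purrr::map(geoms, function(gm) {
    if (is.null(dim(gm))) gm <- matrix(gm, ncol = 2, byrow = TRUE)
    gm <- as.matrix(gm)
    if (ncol(gm) != 2 || !is.numeric(gm) || anyNA(gm))
      stop("geometries must be numeric (x, y) matrices without NA",
           call. = FALSE)
    if (kind == "line" && nrow(gm) < 2)
      stop("line features need at least 2 vertices", call. = FALSE)
    if (kind == "polygon" && nrow(gm) < 3)
      stop("polygon features need at least 3 vertices", call. = FALSE)
    unname(gm)
  })
  out <- tibble::tibble(feature_id = seq_along(geoms), geom = geoms)
  if (!is.null(data)) {
    stopifnot(nrow(data) == length(geoms))
    out <- dplyr::bind_cols(out, tibble::as_tibble(data))
  }
  structure(out, kind = kind, crs = crs,
            class = c("hf_features", class(tibble::tibble())))
}

#' @export
print.hf_features <- function(x, ...) {
  cat(sprintf("<hf_features:%s> %d feature(s), crs '%s'\n",
              attr(x, "kind"), nrow(x), attr(x, "crs")))
  if (nrow(x)) NextMethod()
  invisible(x)
}

n_features <- function(x) nrow(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
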