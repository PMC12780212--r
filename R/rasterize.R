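#' Burn vector features onto a grid
#'
#' Converts a [feature_set()] to a raster on `grid`. Lines and points burn
#' every pixel they touch (supercover grid traversal); polygons burn pixels
#' whose centers fall inside the ring. Where features overlap, the maximum
#' burn value wins — consistent with how scored datasets are later combined
#' into pressure layers. Pixels touched by no feature are 0.
#'
#' @param features A [feature_set()].
#' @param grid Target [grid_spec()]; its CRS must match the features' CRS.
#' @param burn A single number, or the name of an attribute column holding
#'   per-feature burn values.
#' @return A continuous `hf_raster`.
#' @examples
#' g <- grid_spec(10, 10, pixel_size = 30)
#' sq <- feature_set("polygon", list(rbind(c(30, 30), c(120, 30),
#'                                         c(120, 120), c(30, 120))))
#' r <- rasterize(sq, g, burn = 10)
#' sum(r == 10)  # 9 pixels: a 90 m x 90 m square on a 30 m grid
#' @export
rasterize <- function(features, grid, burn = 1) {
  stopifnot(inherits(features, "hf_features"), inherits(grid, "hf_grid"))
  if (!identical(attr(features, "crs"), grid$crs))
    stop(sprintf("feature CRS '%s' does not match grid CRS '%s'; ",
                 attr(features, "crs"), grid$crs),
         "reproject during input preparation", call. = FALSE)
  kind <- attr(features, "kind")
  vals <- if (is.character(burn)) {
    if (!burn %in% names(features))
      stop(sprintf("burn attribute '%s' not found", burn), call. = FALSE)
    v <- features[[burn]]
    if (anyNA(v)) stop(sprintf("burn attribute '%s' has NA for feature(s) %s",
                               burn, paste(which(is.na(v)), collapse = ", ")),
                       call. = FALSE)
    as.numeric(v)
  } else rep(as.numeric(burn), n_features(features))

  out <- matrix(0, grid$n_rows, grid$n_cols)
  skipped <- 0L
  for (f in seq_len(n_features(features))) {
    gm <- features$geom[[f]]
    cells <- switch(kind,
      point = point_cells(gm, grid),
      line = line_cells(gm, grid),
      polygon = polygon_cells(gm, grid, f))
    if (is.null(cells) || nrow(cells) == 0) { skipped <- skipped + 1L; next }
    idx <- cells[, 1] + (cells[, 2] - 1) * grid$n_rows
    out[idx] <- pmax(out[idx], vals[f])
  }
  if (skipped > 0)
    warning(sprintf("%d feature(s) fell entirely outside the grid", skipped),
            call. = FALSE)
  raster_layer(out, grid, kind = "continuous")
}

point_cells <- function(gm, grid) {
  cc <- coords_to_cell(grid, gm[, 1], gm[, 2])
  ok <- !is.na(cc$row)
  cbind(cc$row[ok], cc$col[ok])
}

# all pixels touched by the polyline: Amanatides & Woo traversal per segment,
# in unit-grid coordinates (u = fractional column, v = fractional row)
line_cells <- function(gm, grid) {
  px <- grid$pixel_size
  u <- (gm[, 1] - grid$origin_x) / px
  v <- (grid$origin_y - gm[, 2]) / px
  segs <- purrr::map(seq_len(nrow(gm) - 1), function(s)
    dda_cells(u[s], v[s], u[s + 1], v[s + 1]))
  cells <- unique(do.call(rbind, segs))
  ok <- cells[, 1] >= 1 & cells[, 1] <= grid$n_rows &
        cells[, 2] >= 1 & cells[, 2] <= grid$n_cols
  cells[ok, , drop = FALSE]
}

# supercover DDA on the unit grid; returns (row, col) 1-based
dda_cells <- function(u0, v0, u1, v1) {
  eps <- 1e-12
  du <- u1 - u0; dv <- v1 - v0
  cu <- floor(u0); cv <- floor(v0)
  eu <- floor(u1); ev <- floor(v1)
  step_u <- ifelse(du > 0, 1, -1); step_v <- ifelse(dv > 0, 1, -1)
  tmu <- if (abs(du) < eps) Inf else ((cu + (du > 0)) - u0) / du
  tmv <- if (abs(dv) < eps) Inf else ((cv + (dv > 0)) - v0) / dv
  tdu <- if (abs(du) < eps) Inf else abs(1 / du)
  tdv <- if (abs(dv) < eps) Inf else abs(1 / dv)
  cells <- matrix(NA_real_, nrow = abs(eu - cu) + abs(ev - cv) + 1, ncol = 2)
  k <- 1L
  repeat {
    cells[k, ] <- c(cv, cu)
    if ((cu == eu && cv == ev) || k >= nrow(cells)) break
    k <- k + 1L
    if (tmu < tmv) { cu <- cu + step_u; tmu <- tmu + tdu }
    else { cv <- cv + step_v; tmv <- tmv + tdv }
  }
  cells[seq_len(k), , drop = FALSE] + 1
}

polygon_cells <- function(gm, grid, f) {
  if (anyDuplicated(gm[-nrow(gm), , drop = FALSE]))
    stop(sprintf("invalid polygon geometry in feature %d ", f),
         "(self-intersecting ring vertices)", call. = FALSE)
  cc <- pixel_centers(grid)
  px <- grid$pixel_size
  cols <- which(cc$x >= min(gm[, 1]) - px & cc$x <= max(gm[, 1]) + px)
  rows <- which(cc$y >= min(gm[, 2]) - px & cc$y <= max(gm[, 2]) + px)
  if (!length(cols) || !length(rows)) return(NULL)
  xs <- rep(cc$x[cols], each = length(rows))
  ys <- rep(cc$y[rows], times = length(cols))
  inside <- pracma::inpolygon(xs, ys, gm[, 1], gm[, 2], boundary = FALSE)
  cbind(rep(rows, times = length(cols))[inside],
        rep(cols, each = length(rows))[inside])
}
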