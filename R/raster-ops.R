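#' Resample a raster onto a different grid
#'
#' Continuous layers are interpolated bilinearly at the target pixel
#' centers (edge pixels extend outward, so a constant field stays exactly
#' constant). Categorical layers take the modal code among the source
#' pixels whose centers fall inside each target pixel, falling back to the
#' nearest source pixel when the target is finer than the source; new codes
#' are never invented. `NA` propagates in both modes.
#'
#' @param raster An `hf_raster` with a declared `kind`.
#' @param target Target [grid_spec()] (same CRS).
#' @return An `hf_raster` on `target`.
#' @export
resample <- function(raster, target) {
  stopifnot(inherits(raster, "hf_raster"), inherits(target, "hf_grid"))
  src <- attr(raster, "grid")
  if (!identical(src$crs, target$crs))
    stop("resample does not reproject: source and target CRS differ",
         call. = FALSE)
  kind <- attr(raster, "kind")
  if (!kind %in% c("continuous", "categorical"))
    stop("unknown raster kind '", kind, "'", call. = FALSE)
  tc <- pixel_centers(target)
  # fractional source indices of the target centers
  uc <- (tc$x - src$origin_x) / src$pixel_size + 0.5
  vr <- (src$origin_y - tc$y) / src$pixel_size + 0.5
  if (kind == "continuous") {
    uc <- pmin(pmax(uc, 1), src$n_cols)
    vr <- pmin(pmax(vr, 1), src$n_rows)
    xp <- rep(uc, each = target$n_rows)
    yp <- rep(vr, times = target$n_cols)
    z <- pracma::interp2(seq_len(src$n_cols), seq_len(src$n_rows),
                         raster_values(raster), xp, yp)
    raster_layer(matrix(z, target$n_rows, target$n_cols), target,
                 kind = "continuous")
  } else {
    out <- matrix(NA_real_, target$n_rows, target$n_cols)
    sc <- pixel_centers(src)
    tcol <- floor((sc$x - target$origin_x) / target$pixel_size) + 1
    trow <- floor((target$origin_y - sc$y) / target$pixel_size) + 1
    vals <- raster_values(raster)
    srow <- rep(seq_len(src$n_rows), times = src$n_cols)
    scol <- rep(seq_len(src$n_cols), each = src$n_rows)
    tr <- trow[srow]; tcx <- tcol[scol]
    keep <- tr >= 1 & tr <= target$n_rows & tcx >= 1 & tcx <= target$n_cols
    if (any(keep)) {
      cell <- (tcx[keep] - 1) * target$n_rows + tr[keep]
      modes <- vapply(split(as.vector(vals)[keep], cell), modal_code, 0)
      out[as.integer(names(modes))] <- modes
    }
    # target pixels with no contributing source center: nearest neighbour
    empty <- which(is.na(out) & TRUE)
    if (length(empty)) {
      er <- ((empty - 1) %% target$n_rows) + 1
      ec <- ((empty - 1) %/% target$n_rows) + 1
      nnc <- pmin(pmax(round(uc[ec]), 1), src$n_cols)
      nnr <- pmin(pmax(round(vr[er]), 1), src$n_rows)
      out[empty] <- vals[cbind(nnr, nnc)]
    }
    raster_layer(out, target, kind = "categorical")
  }
}

# modal category; ties break to the smallest code for determinism
modal_code <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  tb <- table(v)
  as.numeric(names(tb)[which.max(tb)])
}

#' Distance to the nearest masked pixel
#'
#' Exact Euclidean distance (meters, center-to-center) from every pixel to
#' the nearest "on" pixel of a binary mask. On-pixels are 0. Backed by the
#' exact distance transform in EBImage.
#'
#' @param mask Binary `hf_raster` (0/1, NA treated as 0).
#' @return A continuous `hf_raster` of distances in meters.
#' @export
euclidean_distance <- function(mask) {
  stopifnot(inherits(mask, "hf_raster"))
  g <- attr(mask, "grid")
  m <- raster_values(mask)
  m[is.na(m)] <- 0
  if (!any(m != 0))
    stop("mask has no on-pixels; distance is undefined", call. = FALSE)
  # distmap() returns, for each foreground pixel, the distance to the
  # nearest background pixel -> invert so on-pixels are the background
  d <- EBImage::distmap(1 - (m != 0), metric = "euclidean")
  raster_layer(as.matrix(d) * g$pixel_size, g, kind = "continuous")
}

#' Label connected clusters of a binary mask
#'
#' @param mask Binary `hf_raster`.
#' @param connectivity 4 (rook) or 8 (queen) adjacency.
#' @return A list with `labels` (categorical `hf_raster`, 0 = background)
#'   and `sizes`, a tibble of `cluster` and `n_pixels`.
#' @export
connected_clusters <- function(mask, connectivity = 8) {
  stopifnot(inherits(mask, "hf_raster"), connectivity %in% c(4, 8))
  m <- raster_values(mask)
  m[is.na(m)] <- 0
  lab <- label_components(m != 0, as.integer(connectivity))
  sizes <- tibble::tibble(cluster = integer(), n_pixels = integer())
  if (any(lab > 0)) {
    tb <- tabulate(lab[lab > 0])
    sizes <- tibble::tibble(cluster = seq_along(tb), n_pixels = tb)
  }
  list(labels = raster_layer(matrix(as.numeric(lab), nrow(m), ncol(m)),
                             attr(mask, "grid"), kind = "categorical"),
       sizes = sizes)
}

#' Mask water pixels out of a raster
#'
#' @param raster Layer to mask.
#' @param water Binary `hf_raster` on the same grid; 1 = water.
#' @return `raster` with water pixels set to `NA`.
#' @export
mask_water <- function(raster, water) {
  check_same_grid(raster, water, what = "raster and water mask")
  v <- raster_values(raster)
  w <- raster_values(water)
  v[!is.na(w) & w != 0] <- NA_real_
  raster_like(v, raster)
}
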