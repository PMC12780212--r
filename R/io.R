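#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text raster exchange for the pipeline. The header carries the grid
#' georeferencing (`xllcorner`/`yllcorner` are the lower-left corner, per
#' the format); rows are written top to bottom. `NA` cells are written as
#' the layer's nodata sentinel.
#'
#' @param raster An `hf_raster`.
#' @param path File path (`.asc`).
#' @param kind Layer kind to assign on read.
#' @param crs CRS identifier to assign on read (the format does not store
#'   one).
#' @return `write_ascii_grid()` returns `path` invisibly;
#'   `read_ascii_grid()` returns an `hf_raster`.
#' @export
write_ascii_grid <- function(raster, path) {
  stopifnot(inherits(raster, "hf_raster"))
  g <- attr(raster, "grid")
  nodata <- attr(raster, "nodata")
  v <- raster_values(raster)
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.10g", g$origin_x),
           sprintf("yllcorner %.10g", g$origin_y - g$n_rows * g$pixel_size),
           sprintf("cellsize %.10g", g$pixel_size),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(v, 1, function(r) paste(format(r, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param path File path.
#' @export
read_ascii_grid <- function(path, kind = c("continuous", "categorical"),
                            crs = "local-metric") {
  kind <- match.arg(kind)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body does not match declared dimensions", call. = FALSE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  g <- grid_spec(hdr$nrows, hdr$ncols, pixel_size = hdr$cellsize,
                 origin_x = hdr$xllcorner,
                 origin_y = hdr$yllcorner + hdr$nrows * hdr$cellsize,
                 crs = crs)
  raster_layer(m, g, kind = kind)
}

#' Read and write feature sets as vertex CSV tables
#'
#' One row per vertex with columns `feature_id`, `x`, `y` plus any
#' attribute columns (repeated per vertex), so feature data survive a
#' plain-text round trip without a binary geospatial container.
#'
#' @param features A [feature_set()].
#' @param path File path (`.csv`).
#' @param kind Geometry kind to assign on read.
#' @param crs CRS identifier to assign on read.
#' @return `write_features_csv()` returns `path` invisibly;
#'   `read_features_csv()` returns a [feature_set()].
#' @export
write_features_csv <- function(features, path) {
  stopifnot(inherits(features, "hf_features"))
  attrs <- features[setdiff(names(features), c("geom"))]
  rows <- purrr::map_dfr(seq_len(nrow(features)), function(f) {
    gm <- features$geom[[f]]
    dplyr::bind_cols(attrs[rep(f, nrow(gm)), , drop = FALSE],
                     tibble::tibble(x = gm[, 1], y = gm[, 2]))
  })
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path, kind = c("point", "line", "polygon"),
                              crs = "local-metric") {
  kind <- match.arg(kind)
  df <- utils::read.csv(path)
  if (!all(c("feature_id", "x", "y") %in% names(df)))
    stop("feature CSV needs feature_id, x, y columns", call. = FALSE)
  ids <- unique(df$feature_id)
  geoms <- purrr::map(ids, function(id) {
    sub <- df[df$feature_id == id, , drop = FALSE]
    cbind(sub$x, sub$y)
  })
  attr_cols <- setdiff(names(df), c("feature_id", "x", "y"))
  data <- NULL
  if (length(attr_cols)) {
    data <- df[match(ids, df$feature_id), attr_cols, drop = FALSE]
    rownames(data) <- NULL
  }
  feature_set(kind, geoms, data = data, crs = crs)
}
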