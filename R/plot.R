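#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a raster layer
#'
#' @param object An `hf_raster`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hf_raster
#' @export
autoplot.hf_raster <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
  if (attr(object, "kind") == "categorical")
    p + ggplot2::scale_fill_viridis_c(option = "D", name = "class")
  else
    p + ggplot2::scale_fill_viridis_c(option = "B", name = "value")
}

#' Plot an HF map
#'
#' @param object An `hf_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hf_map
#' @export
autoplot.hf_map <- function(object, ...) {
  autoplot(object$raster) +
    ggplot2::labs(fill = "HF index",
                  title = sprintf("Human footprint (%s%s)", object$version,
                                  if (is.na(object$year)) "" else
                                    paste0(", ", object$year)))
}

#' Plot a travel-time surface
#'
#' @param object An `hf_traveltime`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hf_traveltime
#' @export
autoplot.hf_traveltime <- function(object, ...) {
  h <- object$hours
  h[!is.finite(h)] <- NA
  autoplot(raster_layer(h, object$grid)) +
    ggplot2::labs(fill = "hours", title = "Travel time to built environments")
}

#' Agreement plot of a validation result
#'
#' Scatter of the standardized visual index against the normalized HF
#' index, with the identity line and the tolerance band.
#'
#' @param object An `hf_validation`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hf_validation
#' @export
autoplot.hf_validation <- function(object, ...) {
  tol <- object$metrics$tolerance
  ggplot2::ggplot(object$plots,
                  ggplot2::aes(x = .data$hf_index, y = .data$visual_index)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey40") +
    ggplot2::geom_abline(slope = 1, intercept = c(-tol, tol),
                         linetype = "dashed", colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$stratum)),
                        alpha = 0.7) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "HF index (normalized)", y = "visual index",
                  colour = "stratum")
}
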