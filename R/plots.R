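#' Plot a synthetic scene with its ground-truth boxes
#'
#' @param object a [generate_scene()] scene.
#' @param boxes optional extra box tibble drawn on top (e.g. proposals).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot synthetic_scene
#' @export
autoplot.synthetic_scene <- function(object, boxes = NULL, ...) {
  h <- dim(object$image)[1]; w <- dim(object$image)[2]
  ras <- grDevices::as.raster(unclass(object$image) / 255)
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(ras, xmin = 0, xmax = w, ymin = -h, ymax = 0) +
    ggplot2::geom_rect(
      data = object$gt_boxes,
      ggplot2::aes(xmin = .data$x_min, xmax = .data$x_max,
                   ymin = -.data$y_max, ymax = -.data$y_min),
      fill = NA, colour = "white", linewidth = 0.4) +
    ggplot2::coord_fixed(xlim = c(0, w), ylim = c(-h, 0), expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
  if (!is.null(boxes) && nrow(boxes)) {
    p <- p + ggplot2::geom_rect(
      data = boxes,
      ggplot2::aes(xmin = .data$x_min, xmax = .data$x_max,
                   ymin = -.data$y_max, ymax = -.data$y_min),
      fill = NA, colour = "yellow", linewidth = 0.3, linetype = "22")
  }
  p
}

#' Plot an NMS result: kept vs suppressed boxes
#'
#' @param object an `"nms_result"`.
#' @param scene optional [generate_scene()] scene to draw underneath.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot nms_result
#' @export
autoplot.nms_result <- function(object, scene = NULL, ...) {
  d <- tidy(object)
  p <- if (!is.null(scene)) {
    h <- dim(scene$image)[1]; w <- dim(scene$image)[2]
    ggplot2::ggplot() +
      ggplot2::annotation_raster(grDevices::as.raster(unclass(scene$image) / 255),
                                 xmin = 0, xmax = w, ymin = -h, ymax = 0) +
      ggplot2::coord_fixed(xlim = c(0, w), ylim = c(-h, 0), expand = FALSE)
  } else {
    ggplot2::ggplot() + ggplot2::coord_fixed()
  }
  p +
    ggplot2::geom_rect(
      data = d,
      ggplot2::aes(xmin = .data$x_min, xmax = .data$x_max,
                   ymin = -.data$y_max, ymax = -.data$y_min,
                   colour = .data$status, linetype = .data$status),
      fill = NA, linewidth = 0.5) +
    ggplot2::scale_colour_manual(values = c(kept = "#00d000",
                                            suppressed = "#d04040")) +
    ggplot2::scale_linetype_manual(values = c(kept = "solid",
                                              suppressed = "22")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot a point-prompt sweep as a Dice heat map
#'
#' @param sweep a [run_point_sweep()] result.
#' @return a ggplot.
#' @export
plot_point_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(.data$n_pos, .data$n_neg,
                                      fill = .data$dice)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$dice)),
                       colour = "white", size = 3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "positive points", y = "negative points", fill = "Dice")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
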