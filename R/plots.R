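# ggplot2 visualisation of fields.

#' @export
autoplot.xv_field <- function(object, slice = NULL, arrow_scale = 4, ...) {
  nn <- attr(object, "nnodes")
  if (is.null(slice)) slice <- (nn[1] - 1) %/% 2
  df <- object[object$i == slice & (object$valid | object$replaced), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$x + arrow_scale * .data$w,
                   yend = .data$y + arrow_scale * .data$v,
                   colour = sqrt(.data$u^2 + .data$v^2 + .data$w^2)),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm"))) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "|u| (voxels)", x = "x (voxels)",
                  y = "y (voxels)",
                  title = sprintf("displacement field, z-slice %d", slice))
}

#' @export
plot.xv_field <- function(x, ...) print(autoplot(x, ...))

#' @export
autoplot.xv_expansion <- function(object, slice = NULL, ...) {
  nn <- attr(object, "nnodes")
  if (is.null(slice)) slice <- (nn[1] - 1) %/% 2
  df <- object[object$i == slice & object$valid, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$expansion)) +
    ggplot2::geom_tile(width = attr(object, "spacing"),
                       height = attr(object, "spacing")) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "expansion", x = "x (voxels)", y = "y (voxels)",
                  title = sprintf("expansion field, z-slice %d", slice))
}

#' @export
plot.xv_expansion <- function(x, ...) print(autoplot(x, ...))
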