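# ggplot2 views of the package's result types.

#' @method autoplot point_cloud
#' @export
autoplot.point_cloud <- function(object, projection = c("xz", "xy", "yz"),
                                 color_by = NULL, ...) {
  projection <- match.arg(projection)
  ax <- strsplit(projection, "")[[1]]
  df <- as_tibble(object)
  if (is.null(color_by))
    color_by <- if ("label" %in% names(df)) "label" else NULL
  if (identical(color_by, "label")) {
    cn <- attr(object, "class_names")
    df$label <- if (!is.null(cn)) factor(cn[df$label + 1], levels = cn)
                else factor(df$label)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[ax[1]]],
                                        y = .data[[ax[2]]])) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = attr(object, "sample_id"))
  if (is.null(color_by))
    p + ggplot2::geom_point(size = 0.3, alpha = 0.6)
  else
    p + ggplot2::geom_point(ggplot2::aes(color = .data[[color_by]]),
                            size = 0.3, alpha = 0.8)
}

#' @method autoplot elgcot3d_fit
#' @export
autoplot.elgcot3d_fit <- function(object, ...) {
  h <- object$history
  df <- dplyr::bind_rows(
    tibble(epoch = h$epoch, value = h$train_loss, what = "train loss"),
    tibble(epoch = h$epoch, value = h$val_miou, what = "val mIoU"),
    tibble(epoch = h$epoch, value = h$val_oa, what = "val OA"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~what, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL)
}

#' Confusion-matrix heatmap
#'
#' @param x a `metrics_report`.
#' @param normalize show row-normalized fractions instead of counts.
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(x, normalize = TRUE, ...) {
  cm <- x$confusion
  if (normalize) {
    rs <- rowSums(cm)
    cm <- sweep(cm, 1, pmax(rs, 1), "/")
  }
  df <- as.data.frame(as.table(cm))
  names(df) <- c("true", "predicted", "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = if (normalize) sprintf("%.2f", .data$value)
              else .data$value), color = "white", size = 3) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(fill = if (normalize) "fraction" else "count",
                  title = sprintf("mIoU %.3f, OA %.3f", x$miou, x$oa))
}

#' Attention heatmap of a segmented cloud
#'
#' Renders the spatial-attention point gates of a [segment_points()] result
#' as a brightness map (brighter = more attended), mirroring the usual
#' qualitative view of where the model focuses.
#'
#' @param seg result of [segment_points()] on a model with the enhancement
#'   module.
#' @param projection which 2-D projection to draw.
#' @return a ggplot.
#' @export
plot_attention <- function(seg, projection = c("xz", "xy", "yz")) {
  projection <- match.arg(projection)
  if (is.null(seg$attention)) abort("model has no attention maps")
  ax <- strsplit(projection, "")[[1]]
  df <- as_tibble(seg$cloud)
  df$attention <- seg$attention$point_gates
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                                   color = .data$attention)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_color_viridis_c(option = "inferno") +
    ggplot2::coord_equal()
}
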