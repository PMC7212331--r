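#' Plot a slice with optional mask overlay
#'
#' @param stack a [slice_stack].
#' @param index 1-based slice index.
#' @param masks optional [bone_masks]; femur and patella outlines are
#'   overlaid.
#' @return a ggplot object.
#' @export
plot_slice <- function(stack, index = 1, masks = NULL) {
  img <- stack$slices[[index]]
  df <- data.frame(
    x = as.vector(col(img)) - 1,
    y = as.vector(row(img)) - 1,
    gray = as.vector(img))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$gray)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = stack$ids[index], fill = "gray") +
    ggplot2::theme_minimal()
  if (!is.null(masks)) {
    lab <- masks$labels[[index]]
    mdf <- data.frame(
      x = as.vector(col(lab)) - 1,
      y = as.vector(row(lab)) - 1,
      bone = factor(as.vector(lab), levels = 1:2,
                    labels = c("femur", "patella")))
    mdf <- mdf[!is.na(mdf$bone), ]
    if (nrow(mdf))
      p <- p + ggplot2::geom_tile(data = mdf,
                                  ggplot2::aes(colour = .data$bone),
                                  fill = NA, linewidth = 0.1)
  }
  p
}

#' Plot key points and fitted central planes in the tilt view
#'
#' Projects the pooled key points onto the (y, z) plane together with each
#' bone's fitted central-plane trace, the view in which the patellar tilt
#' angle is easiest to read.
#'
#' @param object a `measurement_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot measurement_report
#' @export
autoplot.measurement_report <- function(object, ...) {
  kp <- object$key_points
  # plane trace along the mean x of each bone's points
  trace <- do.call(rbind, lapply(split(kp, kp$bone), function(d) {
    pl <- if (d$bone[1] == "femur") object$femur_plane else object$patella_plane
    y <- seq(min(d$y_mm), max(d$y_mm), length.out = 50)
    data.frame(bone = d$bone[1], y_mm = y,
               z_mm = pl$a * mean(d$x_mm) + pl$b * y + pl$c)
  }))
  ggplot2::ggplot(kp, ggplot2::aes(x = .data$y_mm, y = .data$z_mm,
                                   colour = .data$bone)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_line(data = trace, linewidth = 0.7) +
    ggplot2::labs(
      x = "y (mm)", y = "z (mm)",
      title = sprintf("PTA %.1f deg%s", object$pta_deg,
                      if (is.na(object$pls_mm)) ""
                      else sprintf(", PLS %.1f mm", object$pls_mm))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
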