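#' Plot a diameter fit: pooled histogram with the Gaussian overlay
#'
#' @param object A `drgq_diameter_fit`.
#' @param binwidth_um Histogram bin width (um).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot drgq_diameter_fit
#' @export
autoplot.drgq_diameter_fit <- function(object, binwidth_um = 2, ...) {
  df <- tibble(diameter_um = object$diameters_um)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diameter_um)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = binwidth_um, fill = "grey80",
                            colour = "grey40") +
    ggplot2::stat_function(fun = dnorm,
                           args = list(mean = object$mean_um, sd = object$sd_um),
                           colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "soma diameter (µm)", y = "density",
                  title = if (nzchar(object$group)) object$group else NULL,
                  subtitle = sprintf("n = %d, mean %.1f µm, sd %.1f µm",
                                     object$n, object$mean_um, object$sd_um)) +
    ggplot2::theme_minimal()
}

# boundary pixels of each instance (pixels with a 4-neighbour outside the
# instance), for QC overlays
.outline_points <- function(labels) {
  lab <- labels$labels
  nr <- nrow(lab)
  edge <- lab > 0L &
    (.shift_mat(lab, 1L, 0L, 0L) != lab | .shift_mat(lab, -1L, 0L, 0L) != lab |
       .shift_mat(lab, 0L, 1L, 0L) != lab | .shift_mat(lab, 0L, -1L, 0L) != lab)
  idx <- which(edge)
  tibble(row = (idx - 1L) %% nr + 1L, col = (idx - 1L) %/% nr + 1L,
         label = lab[idx])
}

#' QC overlay of one channel with instance outlines and puncta markers
#'
#' Renders the channel as a raster (dark = dim), draws the outline pixels
#' of the given label map, and marks detected puncta centroids, for visual
#' audit of the automated masks.
#'
#' @param stack An [image_stack()].
#' @param channel Channel to display.
#' @param labels Optional [label_map()] whose outlines to draw.
#' @param puncta Optional [detect_puncta()] output; component centroids are
#'   marked.
#' @return A ggplot object.
#' @export
plot_section <- function(stack, channel, labels = NULL, puncta = NULL) {
  ch <- get_channel(stack, channel)
  nr <- nrow(ch)
  df <- tibble(row = rep(seq_len(nr), ncol(ch)),
               col = rep(seq_len(ncol(ch)), each = nr),
               intensity = as.vector(ch))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = paste(channel, "(AFU)")) +
    ggplot2::theme_minimal()
  if (!is.null(labels)) {
    p <- p + ggplot2::geom_point(data = .outline_points(labels),
                                 ggplot2::aes(x = .data$col, y = .data$row),
                                 colour = "yellow", size = 0.1)
  }
  if (!is.null(puncta)) {
    comp <- tidyr::unnest(puncta["components"], "components")
    if (nrow(comp)) {
      p <- p + ggplot2::geom_point(data = comp,
                                   ggplot2::aes(x = .data$centroid_col,
                                                y = .data$centroid_row),
                                   colour = "red", shape = 3, size = 1)
    }
  }
  p
}
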