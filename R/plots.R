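#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

image_df <- function(m, dx, dz, value = "value") {
  d <- dim(m)
  out <- tibble::tibble(x = rep(seq_len(d[1]), times = d[2]) * dx,
                        z = rep(seq_len(d[2]), each = d[1]) * dz,
                        value = as.vector(m))
  names(out)[3] <- value
  out
}

#' Plot a power-Doppler image
#'
#' Displays intensity in dB relative to the image maximum (a 40 dB dynamic
#' range by default), depth increasing downwards as in an ultrasound view.
#'
#' @param object A `power_doppler` image.
#' @param dynamic_range_db Display range below the maximum, default 40.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.power_doppler <- function(object, dynamic_range_db = 40, ...) {
  m <- unclass(object)
  ref <- max(m)
  db <- if (ref > 0) 10 * log10(pmax(m / ref, 10^(-dynamic_range_db / 10 - 1)))
        else m
  df <- image_df(db, attr(object, "dx"), attr(object, "dz"), "dB")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z, fill = .data$dB)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(-dynamic_range_db, 0),
                                  oob = scales_squish) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral (mm)", y = "depth (mm)", fill = "dB")
}

# minimal squish so we avoid a scales dependency beyond ggplot2's own
scales_squish <- function(x, range = c(0, 1)) pmin(pmax(x, range[1]), range[2])

#' Plot a quartile segmentation label map
#' @param object A `quartile_seg`.
#' @param dx,dz Pixel pitch in mm for the axes.
#' @param ... Unused.
#' @return A ggplot of the four intensity-quartile classes over the ROI.
#' @export
autoplot.quartile_seg <- function(object, dx = 0.1, dz = 0.1, ...) {
  df <- image_df(object$label_map, dx, dz, "class")
  df <- df[!is.na(df$class), ]
  df$class <- factor(paste0("Q", df$class), levels = paste0("Q", 1:4))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral (mm)", y = "depth (mm)", fill = "quartile")
}

#' Scree plot of a Casorati singular spectrum
#'
#' Singular values on a log scale with the kept blood band shaded; the
#' leading plateau is tissue clutter, the tail the noise floor.
#'
#' @param object A `singular_spectrum`.
#' @param band Optional [clutter_band()] to highlight.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.singular_spectrum <- function(object, band = NULL, ...) {
  df <- tidy.singular_spectrum(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$singular_value)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "singular value index", y = "singular value")
  if (!is.null(band))
    p <- p + ggplot2::annotate("rect", xmin = band$n_tissue, xmax = band$n_noise,
                               ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "red")
  p
}

#' Bar chart of per-range VVF summaries
#' @param partition A `vvf_partition` tibble.
#' @param stat Which summary to plot: `"mean_vvf"` (default), `"n_vessels"`,
#'   `"total_vvf"` or `"vvf_per_vessel"`.
#' @return A ggplot.
#' @export
plot_vvf_ranges <- function(partition, stat = "mean_vvf") {
  abort_if(!stat %in% names(partition), "unknown summary column.")
  ggplot2::ggplot(partition,
                  ggplot2::aes(x = .data$range, y = .data[[stat]])) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "VVF range", y = stat)
}

#' Bar chart of quartile cut-off values by group
#' @param rows Tibble with `level` (or `quartile`), `value` (or `cutoff_db`)
#'   and optionally `group` columns.
#' @return A ggplot of per-quartile means with points overlaid.
#' @export
plot_quartile_cutoffs <- function(rows) {
  if (!"level" %in% names(rows) && "quartile" %in% names(rows))
    rows <- dplyr::rename(rows, level = "quartile")
  if (!"value" %in% names(rows) && "cutoff_db" %in% names(rows))
    rows <- dplyr::rename(rows, value = "cutoff_db")
  if (!"group" %in% names(rows)) rows$group <- "all"
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$level, y = .data$value,
                                     fill = .data$group)) +
    ggplot2::stat_summary(fun = mean, geom = "col",
                          position = ggplot2::position_dodge(width = 0.8),
                          width = 0.7) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.8),
                        alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "quartile", y = "cut-off (dB)", fill = "group")
}
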