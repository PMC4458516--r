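#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_point
#'   geom_vline scale_y_reverse scale_fill_viridis_c labs theme_minimal
#'   facet_wrap stat_summary
#' @export
ggplot2::autoplot

#' Plot a profile map (demograph)
#'
#' Renders the length-sorted profile map as a raster: each horizontal line
#' is one cell, rows run from the shortest (top) to the longest cell, the
#' x axis is normalized axial position. The y axis can be labelled by cell
#' row or by % cell-cycle progression.
#'
#' @param object A `profile_map`.
#' @param y_axis `"cycle"` (percent cell-cycle progression, default) or
#'   `"row"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.profile_map <- function(object, y_axis = c("cycle", "row"), ...) {
  y_axis <- match.arg(y_axis)
  d <- tidy(object)
  if (y_axis == "cycle") {
    d$y <- d$age * 100
    ylab <- "% cell-cycle progression"
  } else {
    d$y <- d$row
    ylab <- "cell (sorted by length)"
  }
  ggplot(d, aes(x = .data$position, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_y_reverse() +
    scale_fill_viridis_c(name = object$channel) +
    labs(x = "normalized axial position", y = ylab) +
    theme_minimal()
}

#' Plot age-class averaged profiles
#'
#' Peak-normalized (or raw mean) class profiles, one facet per age class.
#'
#' @param object An `age_class_summary`.
#' @param normalized Use the peak-normalized profiles (default) or raw
#'   class means.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.age_class_summary <- function(object, normalized = TRUE, ...) {
  col <- if (normalized) "peak_profile" else "mean_profile"
  n_cols <- attr(object, "n_cols")
  keep <- which(object$defined)
  d <- dplyr::bind_rows(lapply(keep, function(k) {
    tibble::tibble(
      class = sprintf("[%.1f, %.1f) n=%d", object$age_lo[k], object$age_hi[k],
                      object$n[k]),
      position = (seq_len(n_cols) - 0.5) / n_cols,
      value = object[[col]][[k]]
    )
  }))
  ggplot(d, aes(x = .data$position, y = .data$value)) +
    geom_line() +
    facet_wrap(~class) +
    labs(x = "normalized axial position",
         y = if (normalized) "fluorescence (peak-normalized)" else "mean fluorescence") +
    theme_minimal()
}

#' Plot extra mid-cell fluorescence against cell-cycle age
#'
#' Per-cell FCplus vs assigned age with class means overlaid; the moment of
#' peak localization, when defined, is marked with a vertical line.
#'
#' @param object A `midcell_stats` tibble.
#' @param n_classes Age classes for the overlaid means.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.midcell_stats <- function(object, n_classes = 10, ...) {
  d <- tibble::as_tibble(object[object$fc_defined, ])
  mom <- detect_moment(object, n_classes = n_classes)
  p <- ggplot(d, aes(x = .data$age, y = .data$fc_plus)) +
    geom_point(alpha = 0.25, size = 0.8) +
    stat_summary(
      aes(x = (ceiling(.data$age * n_classes) - 0.5) / n_classes),
      fun = mean, geom = "line", colour = "red"
    ) +
    labs(x = "cell-cycle age", y = "extra mid-cell fluorescence (FCplus)") +
    theme_minimal()
  if (!is.na(mom)) p <- p + geom_vline(xintercept = mom, linetype = 2)
  p
}
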