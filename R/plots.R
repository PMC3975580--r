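#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a binned track
#'
#' Signal along one chromosome (or a region) as a step line; masked bins
#' leave gaps.
#'
#' @param object A [binned_track].
#' @param chrom Chromosome to draw (default: the first).
#' @param xlim Optional bp range.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot binned_track
#' @export
autoplot.binned_track <- function(object, chrom = NULL, xlim = NULL, ...) {
  chrom <- chrom %||% names(object$values)[1]
  df <- tidy.binned_track(object)
  df <- df[df$chrom == chrom, , drop = FALSE]
  if (!is.null(xlim)) df <- df[df$start >= xlim[1] & df$end <= xlim[2], , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, y = .data$value)) +
    ggplot2::geom_step(na.rm = TRUE) +
    ggplot2::labs(x = paste0(chrom, " position (bp)"),
                  y = paste0(object$kind, " signal")) +
    ggplot2::theme_minimal()
}

#' Heatmap of a site-by-position profile matrix
#'
#' One row per site, sorted as in the matrix (high to low signal by
#' default), one column per position bin.
#'
#' @param object A `profile_matrix` from [site_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot profile_matrix
#' @export
autoplot.profile_matrix <- function(object, ...) {
  df <- tidy.profile_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$site,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "position relative to site (bp)", y = "site rank",
                  fill = "signal") +
    ggplot2::theme_minimal()
}

#' Plot a fragment-length distribution
#'
#' Raw 1-bp histogram with an optional centered 5-bp running-mean smooth
#' (for display only; statistics are always taken on the raw counts).
#'
#' @param object A `size_distribution` from [crossing_size_distribution()].
#' @param smooth Add the 5-bp running-mean line.
#' @param xlim Length range shown.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot size_distribution
#' @export
autoplot.size_distribution <- function(object, smooth = TRUE, xlim = c(21, 500), ...) {
  df <- tidy.size_distribution(object)
  df <- df[df$length >= xlim[1] & df$length <= xlim[2], , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$length, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "grey70") +
    ggplot2::labs(x = "fragment length (bp)", y = "crossing fragments") +
    ggplot2::theme_minimal()
  if (smooth && nrow(df) >= 5) {
    sm <- stats::filter(df$count, rep(1 / 5, 5), sides = 2)
    p <- p + ggplot2::geom_line(data = tibble::tibble(length = df$length,
                                                      count = as.numeric(sm)),
                                na.rm = TRUE, color = "firebrick")
  }
  p
}

#' Plot MNase sensitivity series
#'
#' Occupancy ratio (relative to the first digestion time point) versus
#' digestion time, one line per particle class.
#'
#' @param object A `sensitivity_series` (rows from one or several calls to
#'   [sensitivity_series()] bound together).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sensitivity_series
#' @export
autoplot.sensitivity_series <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$minutes, y = .data$ratio,
                               color = .data$feature)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "MNase digestion (min)",
                  y = "occupancy / occupancy at first time point",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
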