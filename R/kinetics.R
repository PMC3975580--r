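#' Mean occupancy of a track around anchor points
#'
#' For each anchor, the mean of the unmasked bin values over the window
#' `[pos - window/2, pos + window/2)` is taken; the per-anchor means are
#' then averaged. Anchors whose window is entirely masked are ignored; if
#' every anchor is, an error is raised.
#'
#' @param track A [binned_track].
#' @param anchors Data frame with columns `chrom`, `pos`.
#' @param window Window width in bp (even). Default 200 bp, the summit
#'   window used for focal-particle occupancy; use ~150 bp for windows
#'   centered on flanking-nucleosome midpoints.
#' @return Mean occupancy in the track's units.
#' @export
occupancy_at_features <- function(track, anchors, window = 200) {
  stopifnot(inherits(track, "binned_track"), window %% 2 == 0)
  anchors <- tibble::as_tibble(anchors)
  if (nrow(anchors) == 0) stop("empty anchors", call. = FALSE)
  bs <- track$bin_size
  means <- purrr::map_dbl(seq_len(nrow(anchors)), function(i) {
    v <- track$values[[anchors$chrom[i]]]
    if (is.null(v)) stop("unknown chromosome: ", anchors$chrom[i], call. = FALSE)
    lo <- max(pos_to_bin(anchors$pos[i] - window / 2, bs), 1L)
    hi <- min(pos_to_bin(anchors$pos[i] + window / 2 - 1, bs), length(v))
    seg <- v[lo:hi]
    if (all(is.na(seg))) NA_real_ else mean(seg, na.rm = TRUE)
  })
  if (all(is.na(means))) stop("all bins masked at all anchors", call. = FALSE)
  mean(means, na.rm = TRUE)
}

#' MNase sensitivity series for a particle class
#'
#' Quantifies how fast a particle class is lost with progressive MNase
#' digestion: the occupancy around the anchors is computed at every
#' digestion time point and divided by the occupancy at the first time
#' point. Centromeric particles decay faster than canonical nucleosomes, so
#' their ratio falls below the flanking-nucleosome ratio at every
#' post-initial time point.
#'
#' @param tracks A named list of [binned_track]s; names are MNase digestion
#'   times in minutes (e.g. `"1"`, `"2"`, `"5"`, `"10"`).
#' @param anchors Data frame with columns `chrom`, `pos`.
#' @param window Integration window in bp (see [occupancy_at_features()]).
#' @param feature_label Label stored in the output.
#' @return A `sensitivity_series` tibble: `feature`, `minutes`, `occupancy`,
#'   `ratio` (= occupancy / occupancy at the first time point, so the first
#'   ratio is exactly 1).
#' @export
sensitivity_series <- function(tracks, anchors, window = 200,
                               feature_label = "feature") {
  if (length(tracks) < 2) stop("need at least 2 time points", call. = FALSE)
  minutes <- as.numeric(names(tracks))
  if (anyNA(minutes)) stop("track names must be MNase minutes", call. = FALSE)
  o <- order(minutes)
  if (any(duplicated(minutes))) stop("duplicated time points", call. = FALSE)
  minutes <- minutes[o]; tracks <- tracks[o]
  occ <- purrr::map_dbl(tracks, occupancy_at_features, anchors = anchors, window = window)
  if (occ[[1]] <= 0) stop("zero occupancy at first time point", call. = FALSE)
  out <- tibble::tibble(feature = feature_label, minutes = minutes,
                        occupancy = unname(occ), ratio = unname(occ / occ[[1]]))
  class(out) <- c("sensitivity_series", class(tibble::tibble()))
  out
}

#' Exponential decay rate from a sensitivity series
#'
#' Fits `log(ratio) ~ minutes` by least squares through the observed time
#' points and returns the decay rate lambda (per minute) under the survival
#' model `ratio(t) = exp(-lambda (t - t0))`.
#'
#' @param series A `sensitivity_series`.
#' @return A one-row tibble with `feature`, `lambda`, `r_squared`.
#' @export
fit_decay_rate <- function(series) {
  stopifnot(inherits(series, "sensitivity_series"))
  series |>
    dplyr::group_by(.data$feature) |>
    dplyr::group_modify(function(df, key) {
      fit <- stats::lm(log(ratio) ~ minutes, data = df)
      tibble::tibble(lambda = -unname(stats::coef(fit)[["minutes"]]),
                     r_squared = summary(fit)$r.squared)
    }) |>
    dplyr::ungroup()
}
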