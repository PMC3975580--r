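#' Genome-wide signal threshold from track statistics
#'
#' The site-calling threshold is defined relative to the genome-wide signal:
#' mean plus `k` times the population standard deviation, both computed over
#' unmasked bins. With the defaults used for cenH3 mapping (`k = 7` on the
#' input-subtracted track) this reproduces a threshold of roughly 30
#' normalized counts on deeply sequenced data.
#'
#' @param track A [binned_track].
#' @param k Multiplier on the standard deviation (default 7).
#' @return Threshold in normalized-count units.
#' @export
threshold_from_stats <- function(track, k = 7) {
  stopifnot(inherits(track, "binned_track"))
  v <- unlist(track$values, use.names = FALSE)
  v <- v[!is.na(v)]
  if (length(v) < 2) stop("need at least 2 unmasked bins", call. = FALSE)
  mean(v) + k * sqrt(mean((v - mean(v))^2))
}

# maximal runs of contiguous unmasked bins >= threshold in one vector;
# returns matrix of 1-based [first, last] bin indices
runs_at_or_above <- function(v, threshold) {
  hit <- !is.na(v) & v >= threshold
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(first = starts[r$values], last = ends[r$values])
}

#' Call discrete peaks from input-subtracted tracks
#'
#' Per replicate track, maximal runs of contiguous unmasked bins with value
#' at or above the threshold are found. Runs from different replicates whose
#' intervals overlap are unioned into one candidate site; a candidate is
#' emitted when at least `min_support` replicates contributed a run. The
#' summit is the center of the bin with the maximum replicate-mean signal
#' inside the union (ties broken leftmost); `max_value` is that maximum.
#' Distinct runs separated by any below-threshold bin are never merged, so
#' sites a few hundred bp apart stay distinct.
#'
#' @param diff_tracks A list of difference [binned_track]s (one per
#'   replicate), all on the same grid.
#' @param threshold Calling threshold in normalized-count units (e.g. 30 for
#'   cenH3, 20 for CENP-C, 100 for insoluble chromatin).
#' @param min_support Minimum number of replicates whose run must overlap
#'   the candidate (default 1: a site needs to exceed threshold in at least
#'   one biological replicate).
#' @return A `peak_set` tibble: `chrom`, `run_start`, `run_end`, `summit`,
#'   `max_value`, `support`, sorted by summit within chromosome, with the
#'   threshold and bin size as attributes.
#' @export
call_peaks <- function(diff_tracks, threshold, min_support = 1) {
  if (inherits(diff_tracks, "binned_track")) diff_tracks <- list(diff_tracks)
  if (length(diff_tracks) == 0) stop("empty track list", call. = FALSE)
  stopifnot(threshold > 0, min_support >= 1, min_support <= length(diff_tracks))
  ref <- diff_tracks[[1]]
  for (t in diff_tracks) check_same_grid(ref, t)
  bs <- ref$bin_size

  out <- list()
  for (chrom in names(ref$values)) {
    mats <- lapply(diff_tracks, function(t) runs_at_or_above(t$values[[chrom]], threshold))
    nruns <- vapply(mats, nrow, 0L)
    if (sum(nruns) == 0) next
    allruns <- do.call(rbind, mats)
    rep_id <- rep(seq_along(mats), nruns)
    ir <- IRanges::IRanges(start = allruns[, "first"], end = allruns[, "last"])
    union <- IRanges::reduce(ir)
    hits <- IRanges::findOverlaps(ir, union)
    support <- tapply(rep_id[S4Vectors::queryHits(hits)],
                      S4Vectors::subjectHits(hits),
                      function(x) length(unique(x)))
    support_full <- integer(length(union))
    support_full[as.integer(names(support))] <- as.integer(support)

    vals <- do.call(rbind, lapply(diff_tracks, function(t) t$values[[chrom]]))
    repmean <- colMeans(vals, na.rm = TRUE)
    keep <- which(support_full >= min_support)
    if (length(keep) == 0) next
    rows <- lapply(keep, function(j) {
      first <- IRanges::start(union)[j]; last <- IRanges::end(union)[j]
      seg <- repmean[first:last]
      off <- which.max(seg)  # which.max takes the leftmost of ties
      maxbin <- first + off - 1L
      tibble::tibble(
        chrom = chrom,
        run_start = (first - 1) * bs,
        run_end = min(last * bs, chrom_length(ref$genome, chrom)),
        summit = floor((maxbin - 1) * bs + bs / 2),
        max_value = seg[off],
        support = support_full[j]
      )
    })
    out[[chrom]] <- dplyr::bind_rows(rows)
  }
  peaks <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(chrom = character(), run_start = numeric(), run_end = numeric(),
                   summit = numeric(), max_value = numeric(), support = integer())
  peaks <- dplyr::arrange(peaks, match(.data$chrom, names(ref$values)), .data$summit)
  structure(peaks,
            class = c("peak_set", class(tibble::tibble())),
            threshold = threshold, bin_size = bs,
            genome = ref$genome)
}

#' Fixed-width windows around peak summits
#'
#' Returns the interval `[summit - width/2, summit + width/2)` for every
#' peak, clipped to chromosome bounds, together with the bp coverage of
#' their union (the group coverage used for density normalization).
#'
#' @param peaks A `peak_set` from [call_peaks()], or any tibble with
#'   `chrom` and `summit` columns.
#' @param width Window width in bp; must be even (default 200).
#' @param genome A [genome_build()]; taken from the peak set when omitted.
#' @return A tibble `chrom`, `start`, `end` with attribute
#'   `union_coverage` (bp), also returned by [peak_window_coverage()].
#' @export
peak_windows <- function(peaks, width = 200, genome = attr(peaks, "genome")) {
  stopifnot(width %% 2 == 0, width >= 2)
  win <- tibble::tibble(
    chrom = peaks$chrom,
    start = pmax(peaks$summit - width / 2, 0),
    end = peaks$summit + width / 2
  )
  if (!is.null(genome)) win$end <- pmin(win$end, chrom_length(genome, win$chrom))
  cov <- sum(vapply(split(win, win$chrom), function(df) {
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = df$start + 1, end = df$end))))
  }, 0))
  attr(win, "union_coverage") <- cov
  win
}

#' @rdname peak_windows
#' @param windows Result of [peak_windows()].
#' @export
peak_window_coverage <- function(windows) attr(windows, "union_coverage")

#' @export
print.peak_set <- function(x, ...) {
  cat("<peak_set> ", nrow(x), " peaks at threshold ",
      format(attr(x, "threshold"), digits = 4), "\n", sep = "")
  NextMethod()
}

#' Per-chromosome peak counts and summary
#'
#' @param x A `peak_set`.
#' @param ... Unused.
#' @return A one-row tibble: peak count, threshold, median and maximum peak
#'   signal, replicate-support distribution.
#' @method glance peak_set
#' @export
glance.peak_set <- function(x, ...) {
  tibble::tibble(
    n_peaks = nrow(x),
    threshold = attr(x, "threshold"),
    median_max_value = stats::median(x$max_value),
    max_max_value = if (nrow(x)) max(x$max_value) else NA_real_,
    n_multi_support = sum(x$support > 1)
  )
}

#' Write peaks as BED6 plus a summit TSV
#'
#' @param peaks A `peak_set`.
#' @param path Output BED path; a `.summits.tsv` sidecar holds summit,
#'   max_value and support per peak.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  bed <- tibble::tibble(
    chrom = peaks$chrom, start = peaks$run_start, end = peaks$run_end,
    name = sprintf("peak_%d", seq_len(nrow(peaks))),
    score = signif(peaks$max_value, 6), strand = "."
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  readr::write_tsv(tibble::as_tibble(peaks), paste0(path, ".summits.tsv"))
  invisible(path)
}
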