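#' Fragment size classes
#'
#' MNase protection fragments are partitioned by length into named
#' inclusive classes. The defaults follow the distinction between
#' sub-nucleosome-sized particles and nucleosomes: `small` = 21-140 bp,
#' `nucleosomal` = 141-500 bp. The 140-bp cut is the in silico equivalent
#' of excising the mononucleosome band from a gel.
#'
#' @param classes A named list of length-2 numeric vectors `c(lower, upper)`
#'   (inclusive bp bounds). Ranges must not overlap.
#' @return A `size_class_spec` object.
#' @examples
#' size_class_spec()  # small 21-140, nucleosomal 141-500
#' @export
size_class_spec <- function(classes = list(small = c(21, 140), nucleosomal = c(141, 500))) {
  stopifnot(length(classes) >= 1, !is.null(names(classes)))
  m <- do.call(rbind, classes)
  if (any(m[, 1] > m[, 2])) stop("class lower bound exceeds upper bound", call. = FALSE)
  o <- order(m[, 1])
  if (any(m[o, 1][-1] <= m[o, 2][-nrow(m)])) stop("size classes overlap", call. = FALSE)
  structure(list(classes = classes), class = "size_class_spec")
}

#' Partition fragments by size class
#'
#' Each fragment is assigned to at most one class by its length; fragments
#' outside every class are dropped and tallied.
#'
#' @param frags A [fragment_set()].
#' @param spec A [size_class_spec()].
#' @return A named list of [fragment_set()]s, one per class, with attribute
#'   `dropped` giving the out-of-range count.
#' @export
partition_by_size <- function(frags, spec = size_class_spec()) {
  stopifnot(inherits(spec, "size_class_spec"))
  lab <- frag_labels(frags)
  assigned <- rep(FALSE, nrow(frags))
  out <- purrr::imap(spec$classes, function(rng, nm) {
    sel <- frags$length >= rng[1] & frags$length <= rng[2]
    assigned <<- assigned | sel
    new_fragment_set(tibble::as_tibble(frags)[sel, , drop = FALSE],
                     track = paste0(lab$track, ":", nm),
                     replicate = lab$replicate, mnase_min = lab$mnase_min,
                     condition = lab$condition, skipped = frag_skipped(frags))
  })
  attr(out, "dropped") <- sum(!assigned)
  out
}

#' Length distribution of fragments crossing anchor points
#'
#' A fragment "crosses" an anchor when `start <= pos < end`. Each fragment
#' is counted once per anchor it covers, and the histogram of the counted
#' fragment lengths (1-bp resolution, 1-1000 bp) estimates the protected
#' footprint of the particle centered at the anchors: its mode is the
#' typical protection size (166 bp for lightly digested canonical
#' nucleosomes, 60-100 bp for centromeric particles).
#'
#' @param frags A [fragment_set()].
#' @param anchors A data frame with columns `chrom` and `pos` (bp), e.g.
#'   peak summits or nucleosome dyads.
#' @return A `size_distribution`: histogram tibble accessor via [tidy()],
#'   mode via [distribution_mode()].
#' @export
crossing_size_distribution <- function(frags, anchors) {
  anchors <- tibble::as_tibble(anchors)
  if (nrow(anchors) == 0) stop("empty anchors", call. = FALSE)
  stopifnot(all(c("chrom", "pos") %in% names(anchors)))
  counts <- numeric(1000)
  n_total <- 0
  for (chrom in unique(anchors$chrom)) {
    a <- anchors$pos[anchors$chrom == chrom]
    sel <- frags$chrom == chrom
    if (!any(sel)) next
    fr <- IRanges::IRanges(start = frags$start[sel] + 1, end = frags$end[sel])
    pts <- IRanges::IRanges(start = a + 1, width = 1)
    hits <- IRanges::findOverlaps(pts, fr)
    lens <- frags$length[sel][S4Vectors::subjectHits(hits)]
    lens <- lens[lens >= 1 & lens <= 1000]
    counts <- counts + tabulate(lens, nbins = 1000)
    n_total <- n_total + length(lens)
  }
  structure(list(counts = counts, n_total = n_total,
                 anchor_label = attr(anchors, "label") %||% "anchors",
                 n_anchors = nrow(anchors)),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat("<size_distribution> ", x$n_total, " crossing fragments over ",
      x$n_anchors, " anchors; mode = ", distribution_mode(x), " bp\n", sep = "")
  invisible(x)
}

#' @method tidy size_distribution
#' @export
tidy.size_distribution <- function(x, ...) {
  tibble::tibble(length = seq_along(x$counts), count = x$counts)
}

#' Modal fragment length of a size distribution
#'
#' Ties are broken toward the smaller length (a conservative particle-size
#' estimate). Statistics are always taken on the raw 1-bp histogram;
#' smoothing is for plotting only.
#'
#' @param dist A `size_distribution`.
#' @return Length in bp, or `NA` for an empty distribution.
#' @export
distribution_mode <- function(dist) {
  stopifnot(inherits(dist, "size_distribution"))
  if (dist$n_total == 0) return(NA_real_)
  which.max(dist$counts)  # leftmost maximum = smaller length on ties
}

#' Width of an averaged signal peak at half height
#'
#' Estimates a particle footprint from an averaged occupancy profile. The
#' baseline is the median signal over the outer 10% of positions on each
#' side; the half level is `baseline + (max - baseline) / 2`; the width is
#' the distance between the two half-level crossings found by linear
#' interpolation while moving outward from the maximum.
#'
#' @param profile A data frame with columns `position` (bp, increasing,
#'   evenly spaced) and `value`, or a numeric vector (positions taken as
#'   `seq_along - 1`).
#' @return Width in bp.
#' @export
half_height_width <- function(profile) {
  if (is.numeric(profile) && is.null(dim(profile))) {
    profile <- tibble::tibble(position = seq_along(profile) - 1, value = profile)
  }
  profile <- tibble::as_tibble(profile)
  stopifnot(all(c("position", "value") %in% names(profile)))
  x <- profile$position; y <- profile$value
  o <- order(x); x <- x[o]; y <- y[o]
  n <- length(x)
  k <- max(1L, floor(n * 0.10))
  baseline <- stats::median(c(y[seq_len(k)], y[seq.int(n - k + 1L, n)]))
  imax <- which.max(y)
  half <- baseline + (y[imax] - baseline) / 2

  cross_out <- function(idx_seq) {
    prev <- imax
    for (i in idx_seq) {
      if (y[i] <= half) {
        # interpolate between the inner point (above) and this point
        frac <- (y[prev] - half) / (y[prev] - y[i])
        return(x[prev] + frac * (x[i] - x[prev]))
      }
      prev <- i
    }
    stop("unbounded peak", call. = FALSE)
  }
  left <- if (imax == 1) stop("unbounded peak", call. = FALSE) else
    cross_out(seq.int(imax - 1L, 1L))
  right <- if (imax == n) stop("unbounded peak", call. = FALSE) else
    cross_out(seq.int(imax + 1L, n))
  right - left
}

#' Locate the positioned nucleosomes flanking a site
#'
#' Given an averaged nucleosomal-size signal profile centered on sites,
#' returns the positions of the maxima to the left of `-exclusion_radius`
#' and right of `+exclusion_radius` — the midpoints of the two flanking
#' nucleosomes. Ties break toward the position nearest the center.
#'
#' @param profile Data frame with columns `position` (bp relative to the
#'   site center) and `value`.
#' @param exclusion_radius Half-width of the central zone to ignore
#'   (default 75 bp, just over half a nucleosome).
#' @return Named numeric vector `c(left = ..., right = ...)`.
#' @export
locate_flanking_nucleosomes <- function(profile, exclusion_radius = 75) {
  profile <- tibble::as_tibble(profile)
  stopifnot(all(c("position", "value") %in% names(profile)))
  pick <- function(df) {
    if (nrow(df) == 0 || all(!is.finite(df$value))) {
      stop("no flanking maxima", call. = FALSE)
    }
    m <- max(df$value, na.rm = TRUE)
    cand <- df$position[which(df$value == m)]
    cand[which.min(abs(cand))]
  }
  if (length(unique(profile$value[is.finite(profile$value)])) <= 1) {
    stop("no flanking maxima", call. = FALSE)
  }
  left <- pick(profile[profile$position < -exclusion_radius, , drop = FALSE])
  right <- pick(profile[profile$position > exclusion_radius, , drop = FALSE])
  c(left = left, right = right)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
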