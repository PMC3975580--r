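#' Binned genome tracks
#'
#' A `binned_track` holds one fixed-width signal vector per chromosome
#' (default 10-bp bins). `kind` records where it sits in the pipeline:
#' `raw` fragment counts, `normalized` counts (raw divided by the total
#' count and scaled by the number of unmasked bases in the genome, so the
#' genome-wide mean equals the bin size), `difference` (ChIP minus input)
#' or `log2ratio`. Masked bins — those overlapping the genome build's
#' excluded regions — are stored as `NA` and excluded from every mean,
#' standard deviation, threshold and peak call; they are never treated as
#' zero.
#'
#' @name binned_track
NULL

new_binned_track <- function(values, genome, bin_size, kind, counting_mode = "midpoint") {
  structure(list(values = values, genome = genome, bin_size = bin_size,
                 kind = kind, counting_mode = counting_mode),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat("<binned_track> kind=", x$kind, " bin=", x$bin_size, "bp ",
      sum(lengths(x$values)), " bins (", sum(vapply(x$values, function(v) sum(is.na(v)), 0)),
      " masked)\n", sep = "")
  invisible(x)
}

#' Count fragments into fixed-width bins
#'
#' In `midpoint` mode (the default) each fragment adds one count to the bin
#' containing `floor((start + end) / 2)`, so the total count equals the
#' number of fragments exactly. In `coverage` mode each fragment adds one
#' count to every bin it overlaps, which suits occupancy-style profiles.
#'
#' @param frags A [fragment_set()].
#' @param genome A [genome_build()].
#' @param bin_size Bin width in bp (default 10).
#' @param counting_mode `"midpoint"` or `"coverage"`.
#' @return A raw [binned_track].
#' @export
bin_fragments <- function(frags, genome, bin_size = 10,
                          counting_mode = c("midpoint", "coverage")) {
  counting_mode <- match.arg(counting_mode)
  stopifnot(bin_size >= 1)
  nb <- stats::setNames(n_bins(genome, bin_size), genome$chroms$chrom)
  values <- lapply(nb, function(n) numeric(n))
  if (nrow(frags) > 0) {
    split_idx <- split(seq_len(nrow(frags)), frags$chrom)
    for (chrom in names(split_idx)) {
      i <- split_idx[[chrom]]
      n <- nb[[chrom]]
      if (counting_mode == "midpoint") {
        mid <- floor((frags$start[i] + frags$end[i]) / 2)
        values[[chrom]] <- as.numeric(tabulate(pos_to_bin(mid, bin_size), nbins = n))
      } else {
        first <- pos_to_bin(frags$start[i], bin_size)
        last <- pmin(pos_to_bin(frags$end[i] - 1, bin_size), n)
        delta <- numeric(n + 1)
        add <- tabulate(first, nbins = n + 1)
        sub <- tabulate(last + 1L, nbins = n + 1)
        values[[chrom]] <- cumsum(add - sub)[seq_len(n)]
      }
    }
  }
  new_binned_track(values, genome, bin_size, kind = "raw", counting_mode = counting_mode)
}

# bp spanned by the unmasked bins of a track
unmasked_bases <- function(track) {
  tot <- 0
  for (chrom in names(track$values)) {
    w <- bin_widths(chrom_length(track$genome, chrom), track$bin_size)
    tot <- tot + sum(w[!is.na(track$values[[chrom]])])
  }
  tot
}

#' Normalize a raw track to sequencing depth
#'
#' Each bin's count is divided by the total count over all unmasked bins and
#' scaled by the number of unmasked bases in the genome. Consequence: the
#' sum of all unmasked normalized bins equals the unmasked genome length,
#' and with full-width bins the genome-wide mean normalized value equals the
#' bin size.
#'
#' @param raw A raw [binned_track].
#' @return A normalized [binned_track].
#' @export
normalize_track <- function(raw) {
  stopifnot(inherits(raw, "binned_track"))
  if (raw$kind != "raw") stop("normalize_track() expects a raw track", call. = FALSE)
  total <- sum(vapply(raw$values, function(v) sum(v, na.rm = TRUE), 0))
  if (total <= 0) stop("empty track cannot be normalized", call. = FALSE)
  scale <- unmasked_bases(raw) / total
  out <- raw
  out$values <- lapply(raw$values, function(v) v * scale)
  out$kind <- "normalized"
  out
}

check_same_grid <- function(a, b) {
  if (a$bin_size != b$bin_size ||
      !identical(names(a$values), names(b$values)) ||
      !identical(lengths(a$values), lengths(b$values))) {
    stop("tracks are on different bin grids", call. = FALSE)
  }
}

#' Subtract one normalized track from another
#'
#' Removes background by subtracting the input signal from a ChIP signal,
#' bin by bin. The input is treated as a blank experiment: the result may be
#' negative. A bin masked on either side is masked in the output.
#'
#' @param a,b Normalized [binned_track]s on the same grid (`a - b`).
#' @return A difference [binned_track].
#' @export
subtract_track <- function(a, b) {
  stopifnot(inherits(a, "binned_track"), inherits(b, "binned_track"))
  if (a$kind != "normalized" || b$kind != "normalized") {
    stop("subtract_track() expects normalized tracks", call. = FALSE)
  }
  check_same_grid(a, b)
  out <- a
  out$values <- purrr::map2(a$values, b$values, `-`)
  out$kind <- "difference"
  out
}

#' Windowed log2 ratio of two tracks
#'
#' Means of both tracks are taken over non-overlapping windows, a
#' pseudocount is added to both sides, and the log2 ratio is returned as a
#' track re-binned at the window size. Windows where both means are zero
#' give 0 (the pseudocount guards the ratio); windows fully masked on either
#' side are masked.
#'
#' @param a,b [binned_track]s on the same grid.
#' @param window Window size in bp; must be a multiple of the bin size.
#' @param pseudocount Added to both window means, in normalized-count units.
#' @return A log2ratio [binned_track] with `bin_size = window`.
#' @export
log2_ratio_track <- function(a, b, window = 10000, pseudocount = 1) {
  stopifnot(inherits(a, "binned_track"), inherits(b, "binned_track"))
  check_same_grid(a, b)
  if (window < a$bin_size) stop("window must be >= bin_size", call. = FALSE)
  if (window %% a$bin_size != 0) stop("window must be a multiple of bin_size", call. = FALSE)
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  per <- window / a$bin_size
  win_mean <- function(v) {
    nw <- ceiling(length(v) / per)
    grp <- rep(seq_len(nw), each = per, length.out = length(v))
    m <- tapply(v, grp, function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
    as.numeric(m)
  }
  out <- a
  out$values <- purrr::map2(a$values, b$values, function(va, vb) {
    log2((win_mean(va) + pseudocount) / (win_mean(vb) + pseudocount))
  })
  out$bin_size <- window
  out$kind <- "log2ratio"
  out
}

#' Mask excluded regions of a track
#'
#' Every bin overlapping an excluded interval of the track's genome build is
#' set to `NA`. Masking is idempotent and propagates through all downstream
#' statistics. Usual pipeline order: bin, mask, then normalize, so the
#' normalization total is computed over unmasked bins only.
#'
#' @param track A [binned_track].
#' @return The track with excluded bins masked.
#' @export
mask_regions <- function(track) {
  stopifnot(inherits(track, "binned_track"))
  excl <- track$genome$excluded
  if (nrow(excl) == 0) return(track)
  for (i in seq_len(nrow(excl))) {
    chrom <- excl$chrom[i]
    v <- track$values[[chrom]]
    first <- pos_to_bin(excl$start[i], track$bin_size)
    last <- min(pos_to_bin(excl$end[i] - 1, track$bin_size), length(v))
    v[first:last] <- NA_real_
    track$values[[chrom]] <- v
  }
  track
}

#' Tidy a binned track into a tibble
#'
#' @param x A [binned_track].
#' @param drop_masked Drop masked (`NA`) bins.
#' @param ... Unused.
#' @return A tibble with `chrom`, `start`, `end`, `value`.
#' @method tidy binned_track
#' @export
tidy.binned_track <- function(x, drop_masked = FALSE, ...) {
  out <- purrr::imap(x$values, function(v, chrom) {
    len <- chrom_length(x$genome, chrom)
    start <- (seq_along(v) - 1) * x$bin_size
    tibble::tibble(chrom = chrom, start = start,
                   end = pmin(start + x$bin_size, len), value = v)
  })
  out <- dplyr::bind_rows(out)
  if (drop_masked) out <- out[!is.na(out$value), , drop = FALSE]
  out
}

#' Summary statistics of a binned track
#'
#' @param x A [binned_track].
#' @param ... Unused.
#' @return A one-row tibble with bin counts, mean, population SD, min, max
#'   over unmasked bins.
#' @method glance binned_track
#' @export
glance.binned_track <- function(x, ...) {
  v <- unlist(x$values, use.names = FALSE)
  u <- v[!is.na(v)]
  tibble::tibble(
    kind = x$kind, bin_size = x$bin_size,
    n_bins = length(v), n_masked = sum(is.na(v)),
    mean = mean(u), sd = sqrt(mean((u - mean(u))^2)),
    min = min(u), max = max(u)
  )
}

#' Write a track as bedGraph
#'
#' Four-column bedGraph at bin resolution; masked bins are omitted.
#'
#' @param track A [binned_track].
#' @param path Output path.
#' @param digits Significant digits for values.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, digits = 6) {
  df <- tidy.binned_track(track, drop_masked = TRUE)
  readr::write_tsv(
    dplyr::mutate(df, value = signif(.data$value, digits)),
    path, col_names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a binned track
#'
#' The inverse of [write_bedgraph()] for tracks on a uniform bin grid: bins
#' absent from the file are masked.
#'
#' @param path bedGraph path.
#' @param genome A [genome_build()].
#' @param bin_size Bin width the file was written at.
#' @param kind Track kind to stamp on the result.
#' @return A [binned_track].
#' @export
read_bedgraph <- function(path, genome, bin_size = 10, kind = "normalized") {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric", "numeric"))
  nb <- stats::setNames(n_bins(genome, bin_size), genome$chroms$chrom)
  values <- lapply(nb, function(n) rep(NA_real_, n))
  bad <- setdiff(unique(df$chrom), genome$chroms$chrom)
  if (length(bad)) stop("unknown chromosome: ", bad[[1]], call. = FALSE)
  for (chrom in unique(df$chrom)) {
    sel <- df$chrom == chrom
    idx <- pos_to_bin(df$start[sel], bin_size)
    v <- values[[chrom]]
    v[idx] <- df$value[sel]
    values[[chrom]] <- v
  }
  new_binned_track(values, genome, bin_size, kind = kind)
}
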