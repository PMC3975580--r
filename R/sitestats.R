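#' Site-by-position signal matrix
#'
#' Extracts the binned signal in a window around every anchor (one row per
#' site, one column per bin offset), the input for heatmaps and average
#' profiles. Rows whose window runs past a chromosome end are padded with
#' `NA`. Rows are ordered by descending total signal by default (heatmaps
#' sorted from high to low signal) or by an external key such as the
#' wildtype-minus-depleted difference.
#'
#' @param track A [binned_track].
#' @param anchors Data frame with `chrom`, `pos` columns.
#' @param window Half-window W in bp: columns span `[-W, +W)`. Must be a
#'   multiple of the bin size. Default 1000 (a 2-kb window).
#' @param sort_by `"signal"` (descending row sum), `"none"` (anchor order),
#'   or a numeric vector of length `nrow(anchors)` sorted descending.
#' @return A `profile_matrix`: list with the matrix, the anchor tibble in
#'   row order, and the column offsets (bp, bin centers relative to the
#'   anchor).
#' @export
site_matrix <- function(track, anchors, window = 1000, sort_by = "signal") {
  stopifnot(inherits(track, "binned_track"))
  anchors <- tibble::as_tibble(anchors)
  if (nrow(anchors) == 0) stop("no anchors", call. = FALSE)
  bs <- track$bin_size
  if (window %% bs != 0) stop("window must be a multiple of bin_size", call. = FALSE)
  ncol <- as.integer(2 * window / bs)
  m <- matrix(NA_real_, nrow = nrow(anchors), ncol = ncol)
  for (i in seq_len(nrow(anchors))) {
    v <- track$values[[anchors$chrom[i]]]
    if (is.null(v)) stop("unknown chromosome: ", anchors$chrom[i], call. = FALSE)
    first <- pos_to_bin(anchors$pos[i] - window, bs)
    idx <- seq.int(first, first + ncol - 1L)
    ok <- idx >= 1L & idx <= length(v)
    m[i, ok] <- v[idx[ok]]
  }
  key <- if (is.numeric(sort_by)) {
    stopifnot(length(sort_by) == nrow(anchors))
    sort_by
  } else if (identical(sort_by, "signal")) {
    rowSums(m, na.rm = TRUE)
  } else NULL
  ord <- if (is.null(key)) seq_len(nrow(anchors)) else order(-key)
  structure(list(matrix = m[ord, , drop = FALSE],
                 anchors = anchors[ord, , drop = FALSE],
                 positions = seq(-window, window - bs, by = bs) + bs / 2,
                 bin_size = bs,
                 sort_key = if (is.null(key)) NULL else key[ord]),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("<profile_matrix> ", nrow(x$matrix), " sites x ", ncol(x$matrix),
      " positions (", x$bin_size, "-bp bins)\n", sep = "")
  invisible(x)
}

#' @method tidy profile_matrix
#' @export
tidy.profile_matrix <- function(x, ...) {
  tibble::tibble(
    site = rep(seq_len(nrow(x$matrix)), times = ncol(x$matrix)),
    position = rep(x$positions, each = nrow(x$matrix)),
    value = as.vector(x$matrix)
  )
}

#' Average profile across sites
#'
#' Column means of a [site_matrix()], ignoring missing cells, with the
#' number of contributing sites per position.
#'
#' @param m A `profile_matrix`.
#' @return A tibble `position`, `value`, `n`.
#' @export
average_profile <- function(m) {
  stopifnot(inherits(m, "profile_matrix"))
  if (nrow(m$matrix) == 0) stop("empty matrix", call. = FALSE)
  n <- colSums(!is.na(m$matrix))
  mean <- suppressWarnings(colMeans(m$matrix, na.rm = TRUE))
  mean[n == 0] <- NA_real_
  tibble::tibble(position = m$positions, value = mean, n = n)
}

#' Occupancy summary by interval group
#'
#' For each element of each interval group (e.g. peak windows, broad
#' domains, regions between domains) the mean unmasked signal is computed;
#' each group is then summarized by the five-number summary of its element
#' means. On input-subtracted cenH3 tracks this shows the genome-wide
#' signal hierarchy peaks > domains > between-domains.
#'
#' @param track A [binned_track] (typically a difference track).
#' @param groups A named list of data frames with `chrom`, `start`, `end`.
#' @return A tibble with one row per group: `group`, `n`, `min`, `q1`,
#'   `median`, `q3`, `max` of the per-element means. The per-element means
#'   are attached as attribute `element_means` (named list).
#' @export
group_occupancy_summary <- function(track, groups) {
  stopifnot(inherits(track, "binned_track"), length(groups) >= 1, !is.null(names(groups)))
  bs <- track$bin_size
  el_means <- purrr::map(groups, function(iv) {
    iv <- tibble::as_tibble(iv)
    purrr::map_dbl(seq_len(nrow(iv)), function(i) {
      v <- track$values[[iv$chrom[i]]]
      lo <- max(pos_to_bin(iv$start[i], bs), 1L)
      hi <- min(pos_to_bin(iv$end[i] - 1, bs), length(v))
      seg <- v[lo:hi]
      if (all(is.na(seg))) NA_real_ else mean(seg, na.rm = TRUE)
    })
  })
  rows <- purrr::imap(el_means, function(mns, nm) {
    mns <- mns[!is.na(mns)]
    if (length(mns) == 0) {
      tibble::tibble(group = nm, n = 0L, min = NA_real_, q1 = NA_real_,
                     median = NA_real_, q3 = NA_real_, max = NA_real_)
    } else {
      q <- stats::quantile(mns, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      tibble::tibble(group = nm, n = length(mns), min = q[1], q1 = q[2],
                     median = q[3], q3 = q[4], max = q[5])
    }
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "element_means") <- el_means
  out
}

#' Count elements of one interval set coinciding with another
#'
#' Under the `summit_in_interval` rule an element of `a` (a summit, column
#' `pos`, or an interval whose midpoint is used) counts when its summit lies
#' inside some interval of `b` (half-open: a summit at `end` does not
#' count). Under `any_overlap`, any bp overlap counts. Each element of `a`
#' is counted at most once.
#'
#' @param a Data frame: either summits (`chrom`, `pos`) or intervals
#'   (`chrom`, `start`, `end`).
#' @param b Data frame of intervals (`chrom`, `start`, `end`).
#' @param rule `"summit_in_interval"` or `"any_overlap"`.
#' @return Number of elements of `a` coinciding with `b`.
#' @export
overlap_count <- function(a, b, rule = c("summit_in_interval", "any_overlap")) {
  rule <- match.arg(rule)
  a <- tibble::as_tibble(a); b <- tibble::as_tibble(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(0L)
  a_ir <- function(df) {
    if (rule == "summit_in_interval") {
      pos <- if ("pos" %in% names(df)) df$pos else
        if ("summit" %in% names(df)) df$summit else floor((df$start + df$end) / 2)
      IRanges::IRanges(start = pos + 1, width = 1)
    } else {
      IRanges::IRanges(start = df$start + 1, end = df$end)
    }
  }
  hit <- logical(nrow(a))
  for (chrom in unique(a$chrom)) {
    ai <- which(a$chrom == chrom)
    bi <- b$chrom == chrom
    if (!any(bi)) next
    ira <- a_ir(a[ai, , drop = FALSE])
    irb <- IRanges::IRanges(start = b$start[bi] + 1, end = b$end[bi])
    hit[ai] <- IRanges::overlapsAny(ira, irb)
  }
  sum(hit)
}

#' Coverage-normalized peak densities and fold enrichment
#'
#' Converts per-group peak counts into densities per fixed span of genome
#' (default 10 Mb): `density = n / coverage * per`. The fold ratio between
#' two groups is the ratio of their densities — e.g. insoluble-chromatin
#' peak density at centromeric-site windows vs. broad domains.
#'
#' @param counts Named numeric vector of element counts per group.
#' @param coverages Named numeric vector of bp coverage per group (same
#'   names).
#' @param per Span for density scaling in bp (default 1e7 = 10 Mb).
#' @param ratio_of Length-2 character: groups whose density ratio to report
#'   (numerator, denominator). Default: first two groups.
#' @return A list with `densities` (tibble `group`, `n`, `coverage_bp`,
#'   `density`) and `fold_ratio`.
#' @export
fold_enrichment <- function(counts, coverages, per = 1e7,
                            ratio_of = names(counts)[1:2]) {
  stopifnot(!is.null(names(counts)), setequal(names(counts), names(coverages)))
  coverages <- coverages[names(counts)]
  if (any(coverages <= 0)) stop("zero coverage", call. = FALSE)
  dens <- counts / coverages * per
  num <- dens[[ratio_of[1]]]; den <- dens[[ratio_of[2]]]
  fold <- if (den == 0) {
    if (num == 0) 0 else stop("denominator density is zero", call. = FALSE)
  } else num / den
  list(
    densities = tibble::tibble(group = names(counts), n = unname(counts),
                               coverage_bp = unname(coverages),
                               density = unname(dens)),
    fold_ratio = fold
  )
}

#' Upper-tail hypergeometric overlap test
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): of `N` universe elements `K`
#' are in category B; `n` are drawn (set A); `k_observed` of the draws are
#' in B. Computed via the log-space survival function so p-values down to
#' ~1e-300 are representable.
#'
#' @param N_universe,K,n,k_observed Counts with
#'   `0 <= k_observed <= min(K, n) <= N_universe`.
#' @return Upper-tail p-value.
#' @export
hypergeometric_overlap <- function(N_universe, K, n, k_observed) {
  if (k_observed < 0 || K > N_universe || n > N_universe ||
      k_observed > min(K, n)) {
    stop("inconsistent counts for hypergeometric test", call. = FALSE)
  }
  if (k_observed == 0) return(1)
  exp(stats::phyper(k_observed - 1, m = K, n = N_universe - K, k = n,
                    lower.tail = FALSE, log.p = TRUE))
}

#' Permutation test of summit-interval overlap
#'
#' Re-places the summits of `a` uniformly at random on the unmasked genome
#' (independently per permutation, preserving per-chromosome summit counts)
#' and compares the permuted summit-in-interval overlap with `b` against
#' the observed one. The empirical p-value uses the add-one rule
#' `p = (1 + #permutations at least as extreme) / (n_perm + 1)`.
#'
#' @param a Summits: data frame with `chrom`, `pos` (or `summit`).
#' @param b Intervals: data frame with `chrom`, `start`, `end`.
#' @param genome A [genome_build()]; excluded regions are avoided.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for reproducibility.
#' @param side `"depleted"` (permuted overlap <= observed counts as
#'   extreme) or `"enriched"` (>= observed).
#' @return A one-row tibble: `observed`, `expected` (permutation mean),
#'   `p_value`, `side`, `n_perm`.
#' @export
permutation_overlap_test <- function(a, b, genome, n_perm = 1000, seed = 1,
                                     side = c("depleted", "enriched")) {
  side <- match.arg(side)
  stopifnot(n_perm >= 1)
  a <- tibble::as_tibble(a)
  if (!"pos" %in% names(a)) a$pos <- a$summit
  observed <- overlap_count(a, b, rule = "summit_in_interval")

  # callable (unmasked) segments per chromosome, for uniform placement
  segs <- purrr::pmap_dfr(genome$chroms, function(chrom, length) {
    excl <- genome$excluded[genome$excluded$chrom == chrom, , drop = FALSE]
    ir <- IRanges::setdiff(IRanges::IRanges(1, length),
                           IRanges::IRanges(excl$start + 1, excl$end))
    tibble::tibble(chrom = chrom, start = IRanges::start(ir) - 1,
                   end = as.numeric(IRanges::end(ir)))
  })
  if (sum(segs$end - segs$start) <= 0) stop("no callable genome", call. = FALSE)

  n_per_chrom <- table(a$chrom)
  withr_seed <- function(code) { # local RNG state
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  perm_overlaps <- withr_seed({
    purrr::map_int(seq_len(n_perm), function(p) {
      placed <- purrr::imap_dfr(as.list(n_per_chrom), function(cnt, chrom) {
        s <- segs[segs$chrom == chrom, , drop = FALSE]
        w <- s$end - s$start
        seg_i <- sample.int(nrow(s), cnt, replace = TRUE, prob = w)
        tibble::tibble(chrom = chrom,
                       pos = floor(s$start[seg_i] + stats::runif(cnt) * w[seg_i]))
      })
      as.integer(overlap_count(placed, b, rule = "summit_in_interval"))
    })
  })
  extreme <- if (side == "depleted") sum(perm_overlaps <= observed)
             else sum(perm_overlaps >= observed)
  tibble::tibble(observed = observed, expected = mean(perm_overlaps),
                 p_value = (1 + extreme) / (n_perm + 1),
                 side = side, n_perm = n_perm)
}

#' Windowed Pearson correlation of two tracks
#'
#' Both tracks are averaged over non-overlapping windows (e.g. 10 kb) and
#' the per-window means are compared: Pearson r plus least-squares
#' regression slope and intercept, over windows unmasked on both sides.
#'
#' @param a,b [binned_track]s on the same grid.
#' @param window Window size in bp (multiple of the bin size).
#' @return A one-row tibble: `r`, `slope`, `intercept`, `n_windows`.
#' @export
windowed_correlation <- function(a, b, window = 10000) {
  stopifnot(inherits(a, "binned_track"), inherits(b, "binned_track"))
  check_same_grid(a, b)
  if (window %% a$bin_size != 0) stop("window must be a multiple of bin_size", call. = FALSE)
  per <- window / a$bin_size
  wm <- function(v) {
    nw <- ceiling(length(v) / per)
    grp <- rep(seq_len(nw), each = per, length.out = length(v))
    as.numeric(tapply(v, grp, function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)))
  }
  xa <- unlist(lapply(a$values, wm), use.names = FALSE)
  xb <- unlist(lapply(b$values, wm), use.names = FALSE)
  ok <- !is.na(xa) & !is.na(xb)
  if (sum(ok) < 3) stop("fewer than 3 windows unmasked on both sides", call. = FALSE)
  if (stats::sd(xa[ok]) == 0 || stats::sd(xb[ok]) == 0) {
    stop("zero variance in windowed means", call. = FALSE)
  }
  fit <- stats::lm(xb[ok] ~ xa[ok])
  tibble::tibble(r = stats::cor(xa[ok], xb[ok]),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n_windows = sum(ok))
}

#' Distances between consecutive peaks
#'
#' Summit-to-summit distances between consecutive peaks within each
#' chromosome (never across chromosomes), pooled into a genome-wide
#' summary.
#'
#' @param peaks A `peak_set` or any tibble with `chrom` and `summit`.
#' @return A list with `distances` (tibble `chrom`, `distance`) and
#'   `summary` (one row per chromosome plus a pooled row: `n`, `min`,
#'   `median`, `max`).
#' @export
interpeak_distances <- function(peaks) {
  peaks <- tibble::as_tibble(peaks)
  d <- peaks |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$summit, .by_group = TRUE) |>
    dplyr::reframe(distance = diff(.data$summit))
  if (nrow(d) == 0) stop("need >= 2 peaks on at least one chromosome", call. = FALSE)
  per_chrom <- d |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(n = dplyr::n(), min = min(.data$distance),
                     median = stats::median(.data$distance),
                     max = max(.data$distance), .groups = "drop")
  pooled <- tibble::tibble(chrom = "all", n = nrow(d), min = min(d$distance),
                           median = stats::median(d$distance), max = max(d$distance))
  list(distances = d, summary = dplyr::bind_rows(per_chrom, pooled))
}

#' Feature density around anchors
#'
#' For position bins spanning `[-window/2, +window/2)` around each anchor,
#' the fraction of anchors whose bin overlaps at least one feature interval
#' — e.g. gene density around centromeric sites.
#'
#' @param anchors Data frame `chrom`, `pos`.
#' @param features Data frame `chrom`, `start`, `end`.
#' @param window Total window width in bp (even).
#' @param n_bins Number of position bins across the window.
#' @return A tibble `position` (bin center, bp relative to anchor),
#'   `density` (fraction of anchors, between 0 and 1).
#' @export
feature_density <- function(anchors, features, window = 2000, n_bins = 40) {
  stopifnot(window %% 2 == 0, n_bins >= 1)
  anchors <- tibble::as_tibble(anchors)
  features <- tibble::as_tibble(features)
  bw <- window / n_bins
  edges <- seq(-window / 2, window / 2, length.out = n_bins + 1)
  hits <- matrix(FALSE, nrow = nrow(anchors), ncol = n_bins)
  for (chrom in unique(anchors$chrom)) {
    ai <- which(anchors$chrom == chrom)
    fb <- features[features$chrom == chrom, , drop = FALSE]
    if (nrow(fb) == 0) next
    irb <- IRanges::IRanges(start = fb$start + 1, end = fb$end)
    for (j in seq_len(n_bins)) {
      s <- anchors$pos[ai] + edges[j]
      ira <- IRanges::IRanges(start = s + 1, width = bw)
      hits[ai, j] <- IRanges::overlapsAny(ira, irb)
    }
  }
  tibble::tibble(position = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                 density = colMeans(hits))
}
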