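#' Build a fragment set from a data frame
#'
#' A fragment set is a tibble of paired-end MNase protection fragments
#' (`chrom`, `start`, `end`, `length`; 0-based half-open) carrying sample
#' labels as attributes: which track it is (input, cenH3 ChIP, CENP-C ChIP,
#' insoluble chromatin, ...), the biological replicate, the MNase digestion
#' time in minutes, and the condition (wildtype, knl2-depleted, ...).
#'
#' @param df Data frame with columns `chrom`, `start`, `end`.
#' @param genome Optional [genome_build()]; when given, fragments are
#'   validated against chromosome bounds.
#' @param track,replicate,mnase_min,condition Sample labels.
#' @return A `fragment_set` tibble.
#' @export
fragment_set <- function(df, genome = NULL, track = "track", replicate = 1L,
                         mnase_min = NA_real_, condition = "wildtype") {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  df <- df[, c("chrom", "start", "end")]
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (any(df$start < 0) || any(df$end <= df$start)) {
    stop("fragments must satisfy 0 <= start < end", call. = FALSE)
  }
  if (!is.null(genome)) {
    bad <- setdiff(unique(df$chrom), genome$chroms$chrom)
    if (length(bad)) stop("unknown chromosome: ", bad[[1]], call. = FALSE)
    if (any(df$end > chrom_length(genome, df$chrom))) {
      stop("fragment end beyond chromosome length", call. = FALSE)
    }
  }
  df$length <- df$end - df$start
  new_fragment_set(df, track = track, replicate = replicate,
                   mnase_min = mnase_min, condition = condition,
                   skipped = c(length = 0L, chrom = 0L, malformed = 0L))
}

new_fragment_set <- function(df, track, replicate, mnase_min, condition, skipped) {
  structure(df,
            class = c("fragment_set", class(tibble::tibble())),
            track = track, replicate = replicate,
            mnase_min = mnase_min, condition = condition,
            skipped = skipped)
}

#' Labels and skip tally of a fragment set
#'
#' `frag_labels()` returns the sample labels; `frag_skipped()` the tally of
#' fragments dropped at read time (by length filter, unknown chromosome, or
#' malformed/discordant records).
#'
#' @param frags A [fragment_set()].
#' @return `frag_labels()`: a one-row tibble; `frag_skipped()`: a named
#'   integer vector.
#' @export
frag_labels <- function(frags) {
  tibble::tibble(
    track = attr(frags, "track"),
    replicate = attr(frags, "replicate"),
    mnase_min = attr(frags, "mnase_min"),
    condition = attr(frags, "condition")
  )
}

#' @rdname frag_labels
#' @export
frag_skipped <- function(frags) attr(frags, "skipped")

#' Read paired-end fragments from BED, BEDPE or paired alignments
#'
#' Ingests fragment intervals in one of three dialects:
#' * `"bed"` — 3+ column BED, one fragment per line;
#' * `"bedpe"` — 10-column BEDPE; the two mates are collapsed to their
#'   outermost span (min start, max end). Mates on different chromosomes are
#'   discordant and dropped with a tally;
#' * `"paired_alignments"` — a SAM or BAM file of proper pairs (read via
#'   Rsamtools); each pair yields one fragment from the leftmost mate's
#'   start and its TLEN.
#'
#' Fragments shorter than `min_length`, longer than `max_length`, on unknown
#' chromosomes listed in none of `genome`'s chromosomes, or extending past a
#' chromosome end are dropped and counted in the skip tally returned by
#' [frag_skipped()].
#'
#' @param path Input file path.
#' @param format One of `"bed"`, `"bedpe"`, `"paired_alignments"`.
#' @param genome A [genome_build()].
#' @param min_length,max_length Inclusive fragment-length bounds (bp). The
#'   defaults keep everything the sequencing protocol retains (>25 bp) up to
#'   500 bp, the upper edge of the nucleosomal size class.
#' @param track,replicate,mnase_min,condition Sample labels attached to the
#'   returned set.
#' @return A [fragment_set()].
#' @export
read_fragments <- function(path, format = c("bedpe", "bed", "paired_alignments"),
                           genome, min_length = 26, max_length = 500,
                           track = "track", replicate = 1L,
                           mnase_min = NA_real_, condition = "wildtype") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (min_length < 1) stop("min_length must be >= 1", call. = FALSE)
  skipped <- c(length = 0L, chrom = 0L, malformed = 0L)

  if (format == "bed") {
    df <- read_bed(path)[, c("chrom", "start", "end")]
  } else if (format == "bedpe") {
    lines <- readr::read_lines(path)
    lines <- lines[!grepl("^(#|track)", lines) & nzchar(lines)]
    if (length(lines) == 0) {
      df <- tibble::tibble(chrom = character(), start = numeric(), end = numeric())
    } else {
      fields <- strsplit(lines, "\t", fixed = TRUE)
      nf <- lengths(fields)
      if (any(nf < 6)) stop("malformed BEDPE line ", which(nf < 6)[1], " in ", path, call. = FALSE)
      c1 <- vapply(fields, `[[`, "", 1); s1 <- as.numeric(vapply(fields, `[[`, "", 2))
      e1 <- as.numeric(vapply(fields, `[[`, "", 3))
      c2 <- vapply(fields, `[[`, "", 4); s2 <- as.numeric(vapply(fields, `[[`, "", 5))
      e2 <- as.numeric(vapply(fields, `[[`, "", 6))
      if (anyNA(s1) || anyNA(e1) || anyNA(s2) || anyNA(e2)) {
        stop("malformed BEDPE line ", which(is.na(s1 + e1 + s2 + e2))[1], " in ", path, call. = FALSE)
      }
      concordant <- c1 == c2
      skipped[["malformed"]] <- sum(!concordant)
      df <- tibble::tibble(chrom = c1[concordant],
                           start = pmin(s1, s2)[concordant],
                           end = pmax(e1, e2)[concordant])
    }
  } else {
    df <- read_paired_alignments(path)
  }

  # drop off-chromosome fragments with a tally, then length-filter
  known <- df$chrom %in% genome$chroms$chrom
  skipped[["chrom"]] <- sum(!known)
  df <- df[known, , drop = FALSE]
  if (nrow(df)) {
    inbounds <- df$start >= 0 & df$end <= chrom_length(genome, df$chrom)
    skipped[["chrom"]] <- skipped[["chrom"]] + sum(!inbounds)
    df <- df[inbounds, , drop = FALSE]
  }
  len <- df$end - df$start
  keep <- len >= min_length & len <= max_length
  skipped[["length"]] <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  df$length <- df$end - df$start

  new_fragment_set(df, track = track, replicate = replicate,
                   mnase_min = mnase_min, condition = condition, skipped = skipped)
}

# SAM/BAM proper pairs -> one fragment per pair (leftmost mate + TLEN)
read_paired_alignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading paired alignments requires the Rsamtools package", call. = FALSE)
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isProperPair = TRUE, isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(flag = flag, what = c("rname", "pos", "isize"))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  # exactly one read per proper pair carries TLEN > 0: the leftmost mate;
  # its POS (1-based) and TLEN delimit the sequenced insert
  sel <- !is.na(res$isize) & res$isize > 0
  tibble::tibble(chrom = as.character(res$rname)[sel],
                 start = res$pos[sel] - 1,
                 end = res$pos[sel] - 1 + res$isize[sel])
}

#' @export
print.fragment_set <- function(x, ...) {
  lab <- frag_labels(x)
  cat("<fragment_set> ", nrow(x), " fragments | track=", lab$track,
      " rep=", lab$replicate, " mnase=", lab$mnase_min, "min cond=",
      lab$condition, " | skipped: ",
      paste(names(frag_skipped(x)), frag_skipped(x), sep = "=", collapse = " "),
      "\n", sep = "")
  NextMethod()
}
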