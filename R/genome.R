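#' Construct a genome build
#'
#' A `genome_build` fixes the coordinate frame for the whole pipeline: an
#' ordered set of chromosomes with their lengths, plus optional excluded
#' intervals (typically simple repeats) that are masked out of every
#' downstream mean, threshold and peak call. Coordinates are 0-based
#' half-open throughout, the native BED convention.
#'
#' Excluded intervals are validated against the chromosome bounds, then
#' sorted and merged per chromosome so the stored set is non-overlapping.
#'
#' @param chroms A data frame with columns `chrom` and `length` (bp), or a
#'   named numeric vector of lengths. Chromosome order is preserved.
#' @param excluded Optional data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) of regions to exclude from all analyses.
#' @return A `genome_build` object.
#' @examples
#' gb <- genome_build(c(chrI = 1e6, chrII = 5e5))
#' gb <- genome_build(
#'   tibble::tibble(chrom = "chrI", length = 1e6),
#'   excluded = tibble::tibble(chrom = "chrI", start = 0, end = 100)
#' )
#' @export
genome_build <- function(chroms, excluded = NULL) {
  if (is.numeric(chroms) && !is.null(names(chroms))) {
    chroms <- tibble::tibble(chrom = names(chroms), length = unname(chroms))
  }
  chroms <- tibble::as_tibble(chroms)
  if (!all(c("chrom", "length") %in% names(chroms))) {
    stop("`chroms` needs columns `chrom` and `length`", call. = FALSE)
  }
  chroms <- dplyr::select(chroms, "chrom", "length")
  chroms$chrom <- as.character(chroms$chrom)
  chroms$length <- as.numeric(chroms$length)
  if (anyDuplicated(chroms$chrom)) stop("duplicated chromosome names", call. = FALSE)
  if (any(!is.finite(chroms$length)) || any(chroms$length <= 0)) {
    stop("all chromosome lengths must be > 0", call. = FALSE)
  }

  if (is.null(excluded) || nrow(tibble::as_tibble(excluded)) == 0) {
    excluded <- tibble::tibble(chrom = character(), start = numeric(), end = numeric())
  } else {
    excluded <- tibble::as_tibble(excluded)[, c("chrom", "start", "end")]
    excluded$chrom <- as.character(excluded$chrom)
    bad <- setdiff(unique(excluded$chrom), chroms$chrom)
    if (length(bad)) stop("unknown chromosome in excluded regions: ", bad[[1]], call. = FALSE)
    len <- chroms$length[match(excluded$chrom, chroms$chrom)]
    if (any(excluded$start < 0 | excluded$start >= excluded$end | excluded$end > len)) {
      stop("excluded intervals must satisfy 0 <= start < end <= chrom length", call. = FALSE)
    }
    # merge overlapping/adjacent intervals per chromosome
    excluded <- excluded |>
      dplyr::group_by(.data$chrom) |>
      dplyr::group_modify(function(df, key) {
        ir <- IRanges::reduce(IRanges::IRanges(start = df$start + 1, end = df$end))
        tibble::tibble(start = IRanges::start(ir) - 1, end = as.numeric(IRanges::end(ir)))
      }) |>
      dplyr::ungroup() |>
      dplyr::arrange(match(.data$chrom, chroms$chrom), .data$start)
  }

  structure(list(chroms = chroms, excluded = excluded), class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat("<genome_build> ", nrow(x$chroms), " chromosome(s), ",
      format(sum(x$chroms$length), big.mark = ","), " bp; ",
      nrow(x$excluded), " excluded interval(s), ",
      format(excluded_bases(x), big.mark = ","), " bp excluded\n", sep = "")
  invisible(x)
}

#' Total and unmasked genome size
#'
#' @param genome A [genome_build()].
#' @return Number of bases.
#' @export
genome_bases <- function(genome) {
  stopifnot(inherits(genome, "genome_build"))
  sum(genome$chroms$length)
}

#' @rdname genome_bases
#' @export
excluded_bases <- function(genome) {
  stopifnot(inherits(genome, "genome_build"))
  if (nrow(genome$excluded) == 0) return(0)
  sum(genome$excluded$end - genome$excluded$start)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chroms$chrom)
  if (anyNA(i)) stop("unknown chromosome: ", chrom[which(is.na(i))[1]], call. = FALSE)
  genome$chroms$length[i]
}

n_bins <- function(genome, bin_size) {
  ceiling(genome$chroms$length / bin_size)
}

#' Read a two-column chrom.sizes file
#'
#' @param path Path to a tab- or space-separated file with chromosome name
#'   and length per line.
#' @param excluded Optional path to a BED3 file of excluded regions.
#' @return A [genome_build()].
#' @export
read_chrom_sizes <- function(path, excluded = NULL) {
  df <- utils::read.table(path, header = FALSE, col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  excl <- if (!is.null(excluded)) read_bed(excluded) else NULL
  genome_build(df, excluded = excl)
}

#' Read a BED file into a tibble of intervals
#'
#' Accepts BED3+ (extra columns beyond the sixth are ignored). Returns
#' 0-based half-open intervals; `name`, `score`, `strand` are kept when
#' present.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", which(nf < 3)[1], " in ", path, call. = FALSE)
  }
  out <- tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = as.numeric(vapply(fields, `[[`, "", 2)),
    end   = as.numeric(vapply(fields, `[[`, "", 3))
  )
  if (anyNA(out$start) || anyNA(out$end)) {
    stop("malformed BED line ", which(is.na(out$start) | is.na(out$end))[1],
         " in ", path, call. = FALSE)
  }
  if (all(nf >= 4)) out$name <- vapply(fields, `[[`, "", 4)
  if (all(nf >= 5)) out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5)))
  if (all(nf >= 6)) out$strand <- vapply(fields, `[[`, "", 6)
  out
}

# map genomic positions (0-based) to 1-based bin indices
pos_to_bin <- function(pos, bin_size) floor(pos / bin_size) + 1L

# bp width of every bin on a chromosome (last bin may be partial)
bin_widths <- function(chrom_len, bin_size) {
  nb <- ceiling(chrom_len / bin_size)
  w <- rep(bin_size, nb)
  rem <- chrom_len - (nb - 1) * bin_size
  w[nb] <- rem
  w
}
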