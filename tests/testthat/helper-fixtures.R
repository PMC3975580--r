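# in-code fixtures and independent oracles shared across test files

toy_genome <- function(len = 1000, chrom = "chrI", excluded = NULL) {
  genome_build(stats::setNames(len, chrom), excluded = excluded)
}

# build a binned_track directly from per-chromosome numeric vectors
make_track <- function(v, bin_size = 10, kind = "normalized", chrom = "chrI",
                       genome = NULL) {
  if (!is.list(v)) v <- stats::setNames(list(v), chrom)
  if (is.null(genome)) {
    genome <- genome_build(stats::setNames(lengths(v) * bin_size, names(v)))
  }
  new_binned_track(v, genome, bin_size, kind = kind)
}

# brute-force scanner: maximal runs of contiguous non-NA bins >= thr,
# written independently of runs_at_or_above()
brute_runs <- function(v, thr) {
  out <- NULL
  i <- 1
  while (i <= length(v)) {
    if (!is.na(v[i]) && v[i] >= thr) {
      j <- i
      while (j < length(v) && !is.na(v[j + 1]) && v[j + 1] >= thr) j <- j + 1
      out <- rbind(out, c(i, j))
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# exhaustive hypergeometric upper tail by enumerating all C(N, n) draws:
# elements 1..K are category B; count draws with >= k hits
hyper_enum <- function(N, K, n, k) {
  if (k == 0) return(1)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# fragment tibble helper
frags_df <- function(starts, ends, chrom = "chrI") {
  tibble::tibble(chrom = chrom, start = starts, end = ends)
}

# one default-scale scenario shared by the acceptance tests (built lazily)
.sim_cache <- new.env(parent = emptyenv())
default_scenario <- function() {
  if (is.null(.sim_cache$sim)) .sim_cache$sim <- simulate_scenario(scenario_config(seed = 7))
  .sim_cache$sim
}

normalize_binned <- function(fs, genome, ...) {
  normalize_track(bin_fragments(fs, genome, ...))
}
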