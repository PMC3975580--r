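test_that("genome build validates, merges and reports excluded intervals", {
  gb <- genome_build(c(chrI = 1000, chrII = 500),
                     excluded = tibble::tibble(chrom = c("chrI", "chrI", "chrI"),
                                               start = c(100, 150, 400),
                                               end = c(200, 250, 450)))
  expect_equal(genome_bases(gb), 1500)
  # overlapping 100-200 and 150-250 merge
  expect_equal(nrow(gb$excluded), 2)
  expect_equal(excluded_bases(gb), 200)
  expect_error(genome_build(c(chrI = 0)), "lengths")
  expect_error(genome_build(c(chrI = 100),
                            excluded = tibble::tibble(chrom = "chrI", start = 50, end = 150)),
               "start < end")
  expect_error(genome_build(c(chrI = 100),
                            excluded = tibble::tibble(chrom = "chrX", start = 0, end = 10)),
               "chrX")
})

test_that("BED and BEDPE readers map fields, filter lengths, and tally skips", {
  gb <- toy_genome(10000)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrI\t100\t266\tfrag1\t0\t+"), bed)
  fs <- read_fragments(bed, "bed", gb, min_length = 21, max_length = 500)
  expect_equal(as.numeric(fs[1, c("start", "end", "length")]), c(100, 266, 166))

  bedpe <- withr::local_tempfile(fileext = ".bedpe")
  writeLines(c("chrI\t100\t150\tchrI\t216\t266\tp1\t0\t+\t-",
               "chrI\t300\t350\tchrII\t400\t450\tp2\t0\t+\t-"), bedpe)
  fs <- read_fragments(bedpe, "bedpe", gb, min_length = 21, max_length = 500)
  # outermost span of the mates; discordant-chromosome pair dropped with tally
  expect_equal(nrow(fs), 1)
  expect_equal(as.numeric(fs[1, c("start", "end")]), c(100, 266))
  expect_equal(frag_skipped(fs)[["malformed"]], 1)

  short <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrI\t100\t115\tf\t0\t+", short)
  fs <- read_fragments(short, "bed", gb, min_length = 21, max_length = 500)
  expect_equal(nrow(fs), 0)
  expect_equal(frag_skipped(fs)[["length"]], 1)

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrI\t1\t50\tf\t0\t+", "chrI\toops"), bad)
  expect_error(read_fragments(bad, "bed", gb), "line 2")
})

test_that("paired alignments in SAM yield outermost-span fragments", {
  skip_if_not_installed("Rsamtools")
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chrI\tLN:10000",
    "r1\t99\tchrI\t101\t60\t50M\t=\t217\t166\t*\t*",
    "r1\t147\tchrI\t217\t60\t50M\t=\t101\t-166\t*\t*"
  ), sam)
  fs <- read_fragments(sam, "paired_alignments", toy_genome(10000),
                       min_length = 21, max_length = 500)
  expect_equal(nrow(fs), 1)
  expect_equal(as.numeric(fs[1, c("start", "end", "length")]), c(100, 266, 166))
})

test_that("midpoint binning places counts by fragment midpoint and conserves totals", {
  gb <- toy_genome(1000)
  fs <- fragment_set(frags_df(100, 266), gb)
  tr <- bin_fragments(fs, gb, bin_size = 10, counting_mode = "midpoint")
  v <- tr$values$chrI
  expect_equal(which(v == 1), 19)  # midpoint 183 -> 0-based bin 18
  expect_equal(sum(v), 1)

  cov <- bin_fragments(fs, gb, bin_size = 10, counting_mode = "coverage")
  expect_equal(which(cov$values$chrI == 1), 11:27)  # 0-based bins 10..26

  empty <- fragment_set(frags_df(numeric(0), numeric(0)), gb)
  expect_equal(sum(bin_fragments(empty, gb)$values$chrI), 0)

  # conservation property over random fragment sets
  set.seed(42)
  for (i in 1:5) {
    n <- sample(50:200, 1)
    s <- sample(0:900, n, replace = TRUE)
    fs <- fragment_set(frags_df(s, s + sample(21:90, n, replace = TRUE)), gb)
    expect_equal(sum(bin_fragments(fs, gb)$values$chrI), n)
  }
})

test_that("normalization scales to unmasked genome length", {
  gb <- toy_genome(1000)
  raw <- make_track(c(5, rep(1, 45), rep(0, 54)), kind = "raw", genome = gb)
  norm <- normalize_track(raw)
  expect_equal(norm$values$chrI[1], 5 / 50 * 1000)
  expect_equal(sum(norm$values$chrI), 1000, tolerance = 1e-9)

  uniform <- normalize_track(make_track(rep(1, 100), kind = "raw", genome = gb))
  expect_true(all(abs(uniform$values$chrI - 10) < 1e-12))  # mean = bin_size

  zero <- make_track(rep(0, 100), kind = "raw", genome = gb)
  expect_error(normalize_track(zero), "empty track")
})

test_that("masking excludes bins, is idempotent, and renormalization sums over unmasked bins", {
  gb <- toy_genome(1000, excluded = tibble::tibble(chrom = "chrI", start = 0, end = 100))
  raw <- make_track(rep(1, 100), kind = "raw", genome = gb)
  m1 <- mask_regions(raw)
  expect_true(all(is.na(m1$values$chrI[1:10])))
  expect_true(all(!is.na(m1$values$chrI[11:100])))
  expect_identical(mask_regions(m1)$values, m1$values)

  norm <- normalize_track(m1)
  expect_equal(sum(norm$values$chrI, na.rm = TRUE), 900, tolerance = 1e-9)

  # no excluded regions: identity
  gb2 <- toy_genome(1000)
  raw2 <- make_track(rep(1, 100), kind = "raw", genome = gb2)
  expect_identical(mask_regions(raw2)$values, raw2$values)
})

test_that("track subtraction is exact and propagates masks", {
  a <- make_track(c(42, 10, NA, 7))
  b <- make_track(c(7, 10, 3, NA))
  d <- subtract_track(a, b)
  expect_equal(d$values$chrI, c(35, 0, NA, NA))
  expect_equal(subtract_track(a, a)$values$chrI, c(0, 0, NA, 0))
  expect_error(subtract_track(a, make_track(c(1, 2))), "grids")
})

test_that("windowed log2 ratio matches arithmetic and is zero on identical tracks", {
  a <- make_track(rep(30, 10)); b <- make_track(rep(15, 10))
  lr <- log2_ratio_track(a, b, window = 100, pseudocount = 1)
  expect_equal(lr$values$chrI, log2(31 / 16), tolerance = 1e-12)
  expect_equal(lr$bin_size, 100)
  expect_equal(log2_ratio_track(a, a, window = 50)$values$chrI, rep(0, 2))
  zeros <- make_track(rep(0, 10))
  expect_equal(log2_ratio_track(zeros, zeros, window = 100)$values$chrI, 0)
  expect_error(log2_ratio_track(a, b, window = 5), "bin_size")
})

test_that("bedGraph round-trips a track", {
  gb <- toy_genome(200)
  tr <- normalize_track(make_track(c(rep(2, 10), rep(1, 10)), kind = "raw", genome = gb))
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, gb, bin_size = 10)
  expect_equal(back$values$chrI, tr$values$chrI, tolerance = 1e-5)
})
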