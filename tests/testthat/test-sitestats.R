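test_that("site matrices have anchor-by-position shape and sort by signal", {
  gb <- toy_genome(100000)
  tr <- make_track(rep(3, 10000), genome = gb)
  anch <- data.frame(chrom = "chrI", pos = c(10000, 20000, 30000))
  m <- site_matrix(tr, anch, window = 1000)
  expect_equal(dim(m$matrix), c(3, 200))
  expect_true(all(m$matrix == 3))
  ap <- average_profile(m)
  expect_true(all(ap$value == 3))
  expect_equal(nrow(ap), 200)

  # conservation: mean of row sums equals sum of the average profile
  v <- stats::rpois(10000, 4)
  tr2 <- make_track(as.numeric(v), genome = gb)
  m2 <- site_matrix(tr2, anch, window = 500)
  expect_equal(mean(rowSums(m2$matrix)), sum(average_profile(m2)$value))

  # edge anchor rows are NA-padded, not clipped
  m3 <- site_matrix(tr, data.frame(chrom = "chrI", pos = 100), window = 1000)
  expect_true(anyNA(m3$matrix))
  expect_equal(average_profile(m3)$n[1], 0)

  # external sort key orders rows descending
  key <- c(1, 3, 2)
  m4 <- site_matrix(tr2, anch, window = 500, sort_by = key)
  expect_equal(m4$anchors$pos, c(20000, 30000, 10000))
})

test_that("group occupancy summarises per-element means", {
  gb <- toy_genome(10000)
  v <- rep(0, 1000); v[1:10] <- 5; v[101:110] <- 2; v[201:210] <- 4
  tr <- make_track(v, kind = "difference", genome = gb)
  res <- group_occupancy_summary(tr, list(
    one = data.frame(chrom = "chrI", start = 0, end = 100),
    two = data.frame(chrom = "chrI", start = c(1000, 2000), end = c(1100, 2100)),
    empty = data.frame(chrom = character(), start = numeric(), end = numeric())
  ))
  expect_equal(res$median[res$group == "one"], 5)
  expect_equal(res$median[res$group == "two"], 3)
  expect_equal(res$n[res$group == "empty"], 0)
  expect_true(is.na(res$median[res$group == "empty"]))
})

test_that("overlap counting respects half-open boundaries and the chosen rule", {
  b <- data.frame(chrom = "chrI", start = 100, end = 200)
  expect_equal(overlap_count(data.frame(chrom = "chrI", pos = 150), b), 1L)
  expect_equal(overlap_count(data.frame(chrom = "chrI", pos = 200), b), 0L)
  expect_equal(overlap_count(data.frame(chrom = "chrI", pos = 100), b), 1L)
  expect_equal(overlap_count(data.frame(chrom = "chrI", pos = 500), b), 0L)
  # any-overlap on intervals is symmetric
  a <- data.frame(chrom = "chrI", start = c(150, 300), end = c(250, 400))
  expect_equal(overlap_count(a, b, rule = "any_overlap"), 1L)
  expect_equal(overlap_count(b, a, rule = "any_overlap"), 1L)
  # each element counted at most once even when hitting several intervals
  bb <- data.frame(chrom = "chrI", start = c(100, 140), end = c(160, 200))
  expect_equal(overlap_count(data.frame(chrom = "chrI", pos = 150), bb), 1L)
})

test_that("fold enrichment reproduces density arithmetic on printed counts", {
  fe <- fold_enrichment(c(peaks = 460, domains = 174),
                        c(peaks = 141400, domains = 42722880))
  expect_equal(fe$densities$density, c(460 / 141400 * 1e7, 174 / 42722880 * 1e7))
  expect_equal(round(fe$fold_ratio / 100) * 100, 800)

  fe2 <- fold_enrichment(c(peaks = 163, domains = 26),
                         c(peaks = 141400, domains = 42722880))
  expect_equal(fe2$fold_ratio, (163 / 141400) / (26 / 42722880), tolerance = 1e-12)

  eq <- fold_enrichment(c(a = 10, b = 20), c(a = 1000, b = 2000))
  expect_equal(eq$fold_ratio, 1)

  # scaling both coverages rescales densities but not their ratio
  fe3 <- fold_enrichment(c(peaks = 460, domains = 174),
                         c(peaks = 141400, domains = 42722880) * 3)
  expect_equal(fe3$fold_ratio, fe$fold_ratio, tolerance = 1e-12)
  expect_equal(fe3$densities$density, fe$densities$density / 3, tolerance = 1e-12)
  expect_error(fold_enrichment(c(a = 1, b = 1), c(a = 0, b = 10)), "coverage")
})

test_that("hypergeometric upper tail matches exhaustive enumeration for N <= 12", {
  expect_equal(hypergeometric_overlap(4, 2, 2, 2), 1 / 6, tolerance = 1e-12)
  expect_equal(hypergeometric_overlap(10, 5, 4, 4), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeometric_overlap(100, 50, 40, 0), 1)
  for (N in c(5, 8, 12)) {
    for (K in seq(0, N, by = 2)) {
      for (n in seq(1, N, by = 3)) {
        for (k in 0:min(K, n)) {
          expect_equal(hypergeometric_overlap(N, K, n, k), hyper_enum(N, K, n, k),
                       tolerance = 1e-10)
        }
      }
    }
  }
  # survives extreme tails in log space
  expect_gt(hypergeometric_overlap(30000, 707, 248, 190), 0)
  expect_lt(hypergeometric_overlap(30000, 707, 248, 190), 1e-250)
  expect_error(hypergeometric_overlap(10, 12, 3, 1), "inconsistent")
})

test_that("permutation test is deterministic, degenerate-safe, and detects depletion", {
  gb <- toy_genome(100000)
  a <- data.frame(chrom = "chrI", pos = seq(5000, 95000, length.out = 20))
  whole <- data.frame(chrom = "chrI", start = 0, end = 100000)
  r <- permutation_overlap_test(a, whole, gb, n_perm = 49, seed = 3)
  expect_equal(r$p_value, 1)  # B covers the callable genome: nothing is extreme
  expect_equal(r$observed, 20)

  half <- data.frame(chrom = "chrI", start = 0, end = 50000)
  a0 <- data.frame(chrom = "chrI", pos = seq(51000, 99000, length.out = 20))
  r0 <- permutation_overlap_test(a0, half, gb, n_perm = 999, seed = 5)
  expect_lte(r0$p_value, 0.001)

  r1 <- permutation_overlap_test(a0, half, gb, n_perm = 99, seed = 8)
  r2 <- permutation_overlap_test(a0, half, gb, n_perm = 99, seed = 8)
  expect_identical(r1, r2)
})

test_that("windowed correlation handles exact, anti- and planted correlation", {
  gb <- toy_genome(100000)
  set.seed(31)
  v <- as.numeric(stats::rpois(10000, 6))
  a <- make_track(v, genome = gb)
  expect_equal(windowed_correlation(a, a, window = 1000)$r, 1)
  neg <- make_track(-v, kind = "difference", genome = gb)
  wc <- windowed_correlation(a, neg, window = 1000)
  expect_equal(wc$r, -1)
  expect_equal(wc$slope, -1, tolerance = 1e-12)
  expect_error(windowed_correlation(a, make_track(rep(2, 10000), genome = gb),
                                    window = 1000), "variance")

  # planted window-level correlation rho = 0.5 over 2000 windows
  rho <- 0.5
  nw <- 2000; per <- 10
  z <- stats::rnorm(nw); e <- stats::rnorm(nw)
  wa <- z; wb <- rho * z + sqrt(1 - rho^2) * e
  big <- genome_build(c(chrI = nw * per * 10))
  ta <- make_track(rep(wa, each = per), genome = big)
  tb <- make_track(rep(wb, each = per), genome = big)
  r <- windowed_correlation(ta, tb, window = per * 10)$r
  expect_equal(r, rho, tolerance = 0.05)
})

test_that("inter-peak distances stay within chromosomes", {
  pk <- tibble::tibble(chrom = "chrI", summit = c(100, 390, 1000))
  r <- interpeak_distances(pk)
  expect_equal(sort(r$distances$distance), c(290, 610))
  expect_equal(r$summary$median[r$summary$chrom == "all"], 450)

  two <- tibble::tibble(chrom = c("chrI", "chrII"), summit = c(100, 200))
  expect_error(interpeak_distances(two), "2 peaks")

  shifted <- interpeak_distances(tibble::tibble(chrom = "chrI", summit = c(100, 390, 1000) + 777))
  expect_equal(shifted$distances$distance, r$distances$distance)
})

test_that("feature density reports coverage fractions around anchors", {
  anch <- data.frame(chrom = "chrI", pos = c(10000, 30000))
  all_feat <- data.frame(chrom = "chrI", start = 0, end = 50000)
  d <- feature_density(anch, all_feat, window = 2000, n_bins = 20)
  expect_true(all(d$density == 1))
  none <- feature_density(anch, data.frame(chrom = character(), start = numeric(), end = numeric()),
                          window = 2000, n_bins = 20)
  expect_true(all(none$density == 0))
  # feature at one anchor only -> density 0.5 in covered bins
  one <- feature_density(anch, data.frame(chrom = "chrI", start = 9900, end = 10100),
                         window = 2000, n_bins = 20)
  expect_equal(max(one$density), 0.5)
})
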