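small_cfg <- function(...) {
  args <- utils::modifyList(
    list(seed = 13, chrom_length = 5e5, n_sites = 8, n_domains = 3,
         n_hot = 10, timepoints = c(1, 2), depth = 0.3),
    list(...))
  do.call(scenario_config, args)
}

test_that("identical configurations generate identical datasets and files", {
  s1 <- simulate_scenario(small_cfg())
  s2 <- simulate_scenario(small_cfg())
  expect_identical(s1$truth, s2$truth)
  for (i in seq_len(nrow(s1$fragments))) {
    expect_identical(tibble::as_tibble(s1$fragments$frags[[i]]),
                     tibble::as_tibble(s2$fragments$frags[[i]]))
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_scenario(s1, d1); write_scenario(s2, d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("planted truth respects spacing and boundary invariants", {
  sim <- simulate_scenario(small_cfg())
  sites <- sim$truth$sites
  expect_true(all(diff(sort(sites$pos)) >= 2000))
  expect_true(all(sites$pos >= 1000 & sites$pos <= 5e5 - 1000))
  expect_true(all(sites$protection >= 60 & sites$protection <= 100))
  expect_equal(nrow(sim$truth$dyads), 2 * nrow(sites))
  expect_equal(nrow(sim$truth$hot), 10)
  expect_equal(sum(sim$truth$hot$at_site), 5)  # hot_fraction 0.5
  expect_error(scenario_config(chrom_length = 1e4, n_sites = 100), "2 kb apart")
})

test_that("written scenarios round-trip through the fragment reader", {
  sim <- simulate_scenario(small_cfg(depth = 0.02))
  dir <- withr::local_tempdir()
  write_scenario(sim, dir)
  row <- sim$fragments[3, ]
  name <- sprintf("%s_t%g_rep%d_%s.bedpe", row$track, row$mnase_min,
                  row$replicate, row$condition)
  back <- read_fragments(file.path(dir, name), "bedpe", sim$genome,
                         min_length = 21, max_length = 500)
  orig <- row$frags[[1]]
  key <- function(df) sort(paste(df$chrom, df$start, df$end))
  expect_identical(key(back), key(orig))
  expect_identical(parse_scenario_filename(name)$track, row$track)
  expect_identical(parse_scenario_filename(name)$mnase_min, row$mnase_min)
  # truth JSON reloads consistently
  tr <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(nrow(tr$sites), nrow(sim$truth$sites))
  expect_equal(tr$factors$knl2_factor, sim$config$knl2_factor)
})

test_that("site-particle loss follows the exponential survival model", {
  cfg <- scenario_config(seed = 17, chrom_length = 1e6, n_sites = 30,
                         n_domains = 0, n_hot = 0, timepoints = c(1, 2, 10))
  sim <- simulate_scenario(cfg)
  m <- sim$fragments
  n_site <- function(t, track) {
    sum(m$n_site[m$track == track & m$mnase_min == t & m$condition == "wildtype"])
  }
  expect_equal(n_site(2, "chip") / n_site(1, "chip"),
               exp(-cfg$lambda_cen * 1), tolerance = 0.05)
  r10 <- n_site(10, "chip") / n_site(1, "chip")
  expect_gt(r10, exp(-cfg$lambda_cen * 9) / 2)
  expect_lt(r10, exp(-cfg$lambda_cen * 9) * 2)
  # insoluble site fragments persist at 10 min (slower decay)
  expect_gt(n_site(10, "insoluble") / n_site(1, "insoluble"),
            5 * n_site(10, "chip") / n_site(1, "chip"))
  # nucleosomal linker trimming: mean background length tracks the model
  bg_len <- function(t) {
    fs <- scenario_fragments(sim, "input", t, 1)
    mean(fs$length[fs$length > 120])
  }
  expect_equal(bg_len(1), 147 + 40 * exp(-cfg$lambda_nuc * 1), tolerance = 0.02)
  expect_equal(bg_len(10), 147 + 40 * exp(-cfg$lambda_nuc * 10), tolerance = 0.02)
})

test_that("knl2 depletion reduces site-derived ChIP fragments by the planted factor", {
  sim <- simulate_scenario(small_cfg(depth = 1))
  m <- sim$fragments
  wt <- sum(m$n_site[m$track == "chip" & m$mnase_min == 2 & m$condition == "wildtype"])
  kd <- sum(m$n_site[m$track == "chip" & m$mnase_min == 2 & m$condition == "knl2"])
  expect_equal(kd / wt, 0.15, tolerance = 0.15)
})

test_that("signal hierarchy is peaks > domains > between-domains on ChIP minus input", {
  sim <- simulate_scenario(scenario_config(seed = 19, chrom_length = 1e6, n_sites = 10,
                                           n_domains = 5, n_hot = 0, timepoints = 2))
  gb <- sim$genome
  d <- subtract_track(normalize_binned(scenario_fragments(sim, "chip", 2, 1), gb),
                      normalize_binned(scenario_fragments(sim, "input", 2, 1), gb))
  pw <- peak_windows(tibble::tibble(chrom = sim$truth$sites$chrom,
                                    summit = sim$truth$sites$pos),
                     width = 200, genome = gb)
  dom <- sim$truth$domains
  # regions between domains, avoiding site windows
  gaps <- tibble::tibble(chrom = "chrI",
                         start = c(0, dom$end), end = c(dom$start, 1e6))
  res <- group_occupancy_summary(d, list(peaks = pw, domains = dom, between = gaps))
  med <- stats::setNames(res$median, res$group)
  expect_gt(med[["peaks"]], med[["domains"]])
  expect_gt(med[["domains"]], med[["between"]])
})

test_that("a site-free genome yields essentially no peak calls at mean + 7 SD", {
  sim <- simulate_scenario(scenario_config(seed = 29, chrom_length = 2e6, n_sites = 0,
                                           n_hot = 0, timepoints = 2))
  gb <- sim$genome
  d <- lapply(1:2, function(r) {
    subtract_track(normalize_binned(scenario_fragments(sim, "chip", 2, r), gb),
                   normalize_binned(scenario_fragments(sim, "input", 2, r), gb))
  })
  pk <- call_peaks(d, threshold = threshold_from_stats(d[[1]]))
  expect_lte(nrow(pk), 1)  # < 1 false positive per 10 Mb
})
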