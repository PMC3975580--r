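#' Configuration for a synthetic chromatin scenario
#'
#' Defines the planted chromatin architecture the generator emulates:
#' dispersed point-centromere sites where a sub-nucleosomal particle
#' (60-100 bp protection) sits between two positioned canonical nucleosomes
#' (~150 bp apart on each side), broad ~10-kb domains of mild enrichment
#' producing 135-155 bp fragments, an MNase time course in which
#' centromeric particles decay twice as fast as nucleosomes, a
#' knl2-depleted condition with strongly reduced site-derived ChIP signal,
#' and a HOT-site interval set partially coincident with the planted
#' sites.
#'
#' Fragment lengths follow a phenomenological digestion model: protected
#' core plus a residual linker that erodes exponentially with digestion
#' time (`linker * exp(-lambda_nuc * t)`), plus Gaussian jitter, truncated
#' to 21-500 bp. Particle loss is exponential survival: `exp(-lambda * t)`
#' with `lambda_cen = 2 * lambda_nuc` for centromeric particles and a much
#' slower `lambda_insoluble` for the nuclease-protected insoluble
#' fraction.
#'
#' @param seed Integer seed driving all sampling.
#' @param n_chroms,chrom_length Genome shape (default one 5-Mb chromosome).
#' @param n_sites Planted point-centromere sites (default 50), at least
#'   2 kb apart and 1 kb from chromosome ends.
#' @param site_protection Inclusive bp range the centromeric particle
#'   protects (drawn uniformly per site; default 60-100).
#' @param flank_offset,flank_jitter_sd Flanking nucleosome dyad offsets
#'   from the site center (bp; default +/-150 with SD-10 placement jitter).
#' @param nuc_core,nuc_linker,lambda_nuc Canonical nucleosome protection:
#'   core bp, initial linker bp, and linker/particle decay rate per minute.
#' @param lambda_cen Centromeric particle decay rate (default
#'   `2 * lambda_nuc`).
#' @param lambda_insoluble Site-particle decay rate in the insoluble
#'   fraction (default `0.3 * lambda_cen`; kinetochore binding protects
#'   from nuclease).
#' @param length_jitter_sd,center_jitter_sd Gaussian jitter on fragment
#'   length and particle center (bp).
#' @param n_domains,domain_width,domain_rate Broad mild-enrichment domains
#'   and their extra fragment rate (fragments per bp in input).
#' @param bg_rate Genome-wide background nucleosomal fragment rate
#'   (fragments per bp per track).
#' @param site_weight_input Expected fragments per site in the input at
#'   t = 0.
#' @param chip_enrichment ChIP oversampling of site particles (default 30).
#' @param domain_enrichment ChIP oversampling of domain fragments
#'   (default 2).
#' @param flank_weight_input,flank_weight_chip Expected fragments per
#'   flanking dyad at t = 0 in input and in ChIP/insoluble tracks.
#' @param knl2_factor Multiplier on site-derived ChIP/insoluble fragments
#'   in the knl2-depleted condition (default 0.15).
#' @param hot_fraction Fraction of sites that carry a HOT interval;
#'   `n_hot` total HOT intervals (the remainder are decoys placed away
#'   from sites).
#' @param n_hot Number of HOT intervals.
#' @param timepoints MNase digestion minutes simulated.
#' @param replicates Number of biological replicates.
#' @param depth Global depth multiplier on all fragment rates.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(seed = 7,
                            n_chroms = 1, chrom_length = 5e6,
                            n_sites = 50,
                            site_protection = c(60, 100),
                            flank_offset = 150, flank_jitter_sd = 10,
                            nuc_core = 147, nuc_linker = 40, lambda_nuc = 0.35,
                            lambda_cen = 2 * lambda_nuc,
                            lambda_insoluble = 0.3 * lambda_cen,
                            length_jitter_sd = 8, center_jitter_sd = 6,
                            n_domains = 10, domain_width = 10000, domain_rate = 0.008,
                            bg_rate = 0.05,
                            site_weight_input = 15,
                            chip_enrichment = 30,
                            domain_enrichment = 2,
                            flank_weight_input = 60, flank_weight_chip = 8,
                            knl2_factor = 0.15,
                            hot_fraction = 0.5, n_hot = 60,
                            timepoints = c(1, 2, 5, 10),
                            replicates = 2,
                            depth = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chroms >= 1, cfg$chrom_length > 0, cfg$n_sites >= 0,
            cfg$depth > 0, cfg$bg_rate > 0, cfg$chip_enrichment > 0,
            cfg$knl2_factor > 0, cfg$hot_fraction >= 0, cfg$hot_fraction <= 1,
            length(cfg$timepoints) >= 1, all(diff(cfg$timepoints) > 0),
            cfg$replicates >= 1)
  if (cfg$n_sites * 2000 > (cfg$chrom_length - 2000) * cfg$n_chroms) {
    stop("too many sites for this genome (sites must be >= 2 kb apart)", call. = FALSE)
  }
  structure(cfg, class = "scenario_config")
}

# minimum-spacing uniform placement on [lo, hi]
place_spaced <- function(n, lo, hi, min_gap) {
  if (n == 0) return(numeric(0))
  pos <- numeric(0)
  tries <- 0
  while (length(pos) < n) {
    cand <- floor(stats::runif(1, lo, hi))
    if (length(pos) == 0 || min(abs(pos - cand)) >= min_gap) pos <- c(pos, cand)
    tries <- tries + 1
    if (tries > n * 1000) stop("infeasible placement: too many sites for genome", call. = FALSE)
  }
  sort(pos)
}

nuc_length <- function(cfg, t, n) {
  cfg$nuc_core + cfg$nuc_linker * exp(-cfg$lambda_nuc * t) +
    stats::rnorm(n, 0, cfg$length_jitter_sd)
}

empty_frags <- function() {
  tibble::tibble(chrom = character(), start = numeric(), end = numeric())
}

# fragments centered at `centers` with lengths `len`, clamped to [21, 500]
# and to chromosome bounds
make_frags <- function(chrom, centers, len, chrom_len) {
  len <- pmin(pmax(round(len), 21), 500)
  start <- pmax(round(centers - len / 2), 0)
  end <- pmin(start + len, chrom_len)
  keep <- end - start >= 21
  tibble::tibble(chrom = chrom, start = start[keep], end = end[keep])
}

#' Simulate a full synthetic MNase profiling scenario
#'
#' Generates paired-end fragment sets for input, cenH3-ChIP and insoluble
#' chromatin tracks across an MNase time course and two replicates, in
#' wildtype and knl2-depleted conditions, together with the planted truth
#' (site coordinates and protection sizes, flanking dyads, domains, HOT
#' intervals) and the genome build. All sampling derives from
#' `config$seed`: the same configuration reproduces the identical dataset.
#'
#' Track composition: input tracks carry genome-wide background nucleosomal
#' fragments, positioned flanking nucleosomes at every site, decaying
#' sub-nucleosomal site particles at low rate, and extra domain fragments
#' (135-155 bp). ChIP tracks oversample the site particles by
#' `chip_enrichment` and the domain fragments by `domain_enrichment`; the
#' insoluble track mirrors ChIP at sites but with a much slower decay, so
#' its site signal persists at 10 min. The knl2 condition multiplies
#' site-derived ChIP/insoluble fragments by `knl2_factor` and is simulated
#' at 2 min digestion.
#'
#' @param config A [scenario_config()].
#' @return A `scenario` list: `fragments` — a manifest tibble with label
#'   columns (`track`, `mnase_min`, `replicate`, `condition`), per-component
#'   fragment counts, and a `frags` list-column of [fragment_set()]s;
#'   `truth` — planted sites/dyads/domains/HOT intervals; `genome`;
#'   `config`.
#' @export
simulate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  set.seed(cfg$seed)

  chroms <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                            paste0("chr", utils::as.roman(seq_len(cfg$n_chroms))))
  genome <- genome_build(chroms)

  # --- planted truth ------------------------------------------------------
  per_chrom_sites <- diff(floor(seq(0, cfg$n_sites, length.out = cfg$n_chroms + 1)))
  sites <- purrr::map2_dfr(names(chroms), per_chrom_sites, function(chrom, n) {
    tibble::tibble(chrom = chrom,
                   pos = place_spaced(n, 1000, cfg$chrom_length - 1000, 2000))
  })
  sites$protection <- if (nrow(sites)) {
    floor(stats::runif(nrow(sites), cfg$site_protection[1], cfg$site_protection[2] + 1))
  } else numeric(0)

  dyads <- if (nrow(sites)) {
    dplyr::bind_rows(
      tibble::tibble(chrom = sites$chrom, site = seq_len(nrow(sites)), side = "left",
                     pos = round(sites$pos - cfg$flank_offset +
                                   stats::rnorm(nrow(sites), 0, cfg$flank_jitter_sd))),
      tibble::tibble(chrom = sites$chrom, site = seq_len(nrow(sites)), side = "right",
                     pos = round(sites$pos + cfg$flank_offset +
                                   stats::rnorm(nrow(sites), 0, cfg$flank_jitter_sd)))
    )
  } else tibble::tibble(chrom = character(), site = integer(), side = character(), pos = numeric())

  domains <- purrr::map_dfr(names(chroms), function(chrom) {
    n <- max(0L, round(cfg$n_domains / cfg$n_chroms))
    if (n == 0) return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
    ctr <- place_spaced(n, cfg$domain_width, cfg$chrom_length - cfg$domain_width,
                        2 * cfg$domain_width)
    tibble::tibble(chrom = chrom, start = ctr - cfg$domain_width / 2,
                   end = ctr + cfg$domain_width / 2)
  })

  n_hot_at_site <- min(round(cfg$hot_fraction * cfg$n_hot), nrow(sites))
  hot_site_idx <- if (n_hot_at_site > 0) sort(sample(nrow(sites), n_hot_at_site)) else integer(0)
  hot_at_sites <- tibble::tibble(chrom = sites$chrom[hot_site_idx],
                                 start = sites$pos[hot_site_idx] - 100,
                                 end = sites$pos[hot_site_idx] + 100,
                                 at_site = TRUE)
  n_decoy <- cfg$n_hot - n_hot_at_site
  decoys <- purrr::map_dfr(names(chroms), function(chrom) {
    n <- round(n_decoy / cfg$n_chroms)
    if (n <= 0) return(tibble::tibble(chrom = character(), start = numeric(),
                                      end = numeric(), at_site = logical()))
    ctr <- floor(stats::runif(n, 1000, cfg$chrom_length - 1000))
    tibble::tibble(chrom = chrom, start = ctr - 100, end = ctr + 100, at_site = FALSE)
  })
  hot <- dplyr::arrange(dplyr::bind_rows(hot_at_sites, decoys), .data$chrom, .data$start)

  truth <- list(sites = sites, dyads = dyads, domains = domains, hot = hot,
                factors = list(chip_enrichment = cfg$chip_enrichment,
                               domain_enrichment = cfg$domain_enrichment,
                               knl2_factor = cfg$knl2_factor,
                               lambda_nuc = cfg$lambda_nuc,
                               lambda_cen = cfg$lambda_cen,
                               lambda_insoluble = cfg$lambda_insoluble))

  # --- per-track generation ----------------------------------------------
  gen_set <- function(track, t, rep_id, condition) {
    d <- cfg$depth
    site_lambda <- switch(track, insoluble = cfg$lambda_insoluble, cfg$lambda_cen)
    site_w0 <- switch(track,
                      input = cfg$site_weight_input,
                      cfg$site_weight_input * cfg$chip_enrichment)
    cond_f <- if (condition == "knl2" && track != "input") cfg$knl2_factor else 1
    flank_w <- switch(track, input = cfg$flank_weight_input, cfg$flank_weight_chip)
    dom_f <- switch(track, chip = cfg$domain_enrichment, 1)

    parts <- list()
    # background nucleosomes, genome-wide
    n_bg_per <- stats::rpois(cfg$n_chroms, cfg$bg_rate * cfg$chrom_length * d)
    parts$bg <- purrr::map2_dfr(names(chroms), n_bg_per, function(chrom, n) {
      make_frags(chrom, stats::runif(n, 0, cfg$chrom_length),
                 nuc_length(cfg, t, n), cfg$chrom_length)
    })
    # positioned flanking nucleosomes
    parts$flank <- if (nrow(dyads)) {
      n_fl <- stats::rpois(nrow(dyads), flank_w * exp(-cfg$lambda_nuc * t) * d)
      idx <- rep(seq_len(nrow(dyads)), n_fl)
      make_frags(dyads$chrom[idx],
                 dyads$pos[idx] + stats::rnorm(length(idx), 0, cfg$center_jitter_sd),
                 nuc_length(cfg, t, length(idx)), cfg$chrom_length)
    } else empty_frags()
    # centromeric site particles
    parts$site <- if (nrow(sites)) {
      n_st <- stats::rpois(nrow(sites), site_w0 * exp(-site_lambda * t) * cond_f * d)
      idx <- rep(seq_len(nrow(sites)), n_st)
      len <- sites$protection[idx] + cfg$nuc_linker * exp(-cfg$lambda_nuc * t) +
        stats::rnorm(length(idx), 0, cfg$length_jitter_sd)
      make_frags(sites$chrom[idx],
                 sites$pos[idx] + stats::rnorm(length(idx), 0, cfg$center_jitter_sd),
                 len, cfg$chrom_length)
    } else empty_frags()
    # domain fragments (135-155 bp protection)
    parts$domain <- if (nrow(domains)) {
      n_dm <- stats::rpois(nrow(domains), cfg$domain_rate * (domains$end - domains$start) * dom_f * d)
      idx <- rep(seq_len(nrow(domains)), n_dm)
      ctr <- stats::runif(length(idx), domains$start[idx], domains$end[idx])
      make_frags(domains$chrom[idx], ctr, stats::runif(length(idx), 135, 155),
                 cfg$chrom_length)
    } else empty_frags()

    counts <- vapply(parts, nrow, 0L)
    df <- dplyr::bind_rows(parts)
    fs <- fragment_set(df, genome = genome, track = track, replicate = rep_id,
                       mnase_min = t, condition = condition)
    tibble::tibble(track = track, mnase_min = t, replicate = rep_id,
                   condition = condition,
                   n_bg = counts[["bg"]], n_flank = counts[["flank"]],
                   n_site = counts[["site"]], n_domain = counts[["domain"]],
                   frags = list(fs))
  }

  grid <- dplyr::bind_rows(
    tidyr::expand_grid(track = c("input", "chip", "insoluble"),
                       mnase_min = cfg$timepoints,
                       replicate = seq_len(cfg$replicates),
                       condition = "wildtype"),
    tidyr::expand_grid(track = c("input", "chip"),
                       mnase_min = intersect(2, cfg$timepoints),
                       replicate = seq_len(cfg$replicates),
                       condition = "knl2")
  )
  manifest <- purrr::pmap_dfr(grid, function(track, mnase_min, replicate, condition) {
    gen_set(track, mnase_min, replicate, condition)
  })

  structure(list(fragments = manifest, truth = truth, genome = genome, config = cfg),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> ", nrow(x$fragments), " fragment sets, ",
      nrow(x$truth$sites), " planted sites on ",
      nrow(x$genome$chroms), " chromosome(s) (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Pull one fragment set out of a scenario
#'
#' @param sim A `scenario` from [simulate_scenario()].
#' @param track,mnase_min,replicate,condition Label filters.
#' @return A [fragment_set()].
#' @export
scenario_fragments <- function(sim, track, mnase_min, replicate = 1,
                               condition = "wildtype") {
  m <- sim$fragments
  sel <- m$track == track & m$mnase_min == mnase_min &
    m$replicate == replicate & m$condition == condition
  if (sum(sel) != 1) stop("no unique fragment set with those labels", call. = FALSE)
  m$frags[[which(sel)]]
}

#' Write a scenario to disk as plain-text files
#'
#' One BEDPE per fragment set (named
#' `<track>_t<minutes>_rep<replicate>_<condition>.bedpe`; mates are the
#' outermost 50 bp of each fragment so the outermost-span convention
#' round-trips exactly), plus `chrom.sizes`, truth BED files
#' (`sites.bed`, `domains.bed`, `hot.bed`) and `truth.json`.
#'
#' @param sim A `scenario`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_scenario <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("unwritable path: ", out_dir, call. = FALSE)
  readr::write_tsv(sim$genome$chroms, file.path(out_dir, "chrom.sizes"), col_names = FALSE)
  for (i in seq_len(nrow(sim$fragments))) {
    row <- sim$fragments[i, ]
    fs <- row$frags[[1]]
    name <- sprintf("%s_t%g_rep%d_%s.bedpe", row$track, row$mnase_min,
                    row$replicate, row$condition)
    m1e <- pmin(fs$start + 50, fs$end)
    m2s <- pmax(fs$end - 50, fs$start)
    bedpe <- tibble::tibble(c1 = fs$chrom, s1 = fs$start, e1 = m1e,
                            c2 = fs$chrom, s2 = m2s, e2 = fs$end,
                            name = sprintf("frag%d", seq_len(nrow(fs))),
                            score = 0, strand1 = "+", strand2 = "-")
    readr::write_tsv(bedpe, file.path(out_dir, name), col_names = FALSE)
  }
  tr <- sim$truth
  readr::write_tsv(tibble::tibble(chrom = tr$sites$chrom, start = tr$sites$pos,
                                  end = tr$sites$pos + 1,
                                  name = sprintf("site%d:prot%d", seq_len(nrow(tr$sites)),
                                                 tr$sites$protection)),
                   file.path(out_dir, "sites.bed"), col_names = FALSE)
  readr::write_tsv(tr$domains, file.path(out_dir, "domains.bed"), col_names = FALSE)
  readr::write_tsv(tr$hot, file.path(out_dir, "hot.bed"), col_names = FALSE)
  jsonlite::write_json(
    list(sites = tr$sites, dyads = tr$dyads, domains = tr$domains,
         hot = tr$hot, factors = tr$factors),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Parse a scenario BEDPE file name back into its labels
#'
#' @param path A file written by [write_scenario()].
#' @return A one-row tibble `track`, `mnase_min`, `replicate`, `condition`.
#' @export
parse_scenario_filename <- function(path) {
  m <- regmatches(basename(path),
                  regexec("^(.+)_t([0-9.]+)_rep([0-9]+)_(.+)\\.bedpe$", basename(path)))[[1]]
  if (length(m) != 5) stop("not a scenario BEDPE filename: ", path, call. = FALSE)
  tibble::tibble(track = m[2], mnase_min = as.numeric(m[3]),
                 replicate = as.integer(m[4]), condition = m[5])
}
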