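---
title: "Methods: mapping point-centromere sites from MNase ChIP-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping point-centromere sites from MNase ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holocentr)
library(ggplot2)
```

## The analysis model

`holocentr` implements an analysis pipeline for mapping discrete
centromere sites on holocentric chromosomes from micrococcal-nuclease
(MNase) ChIP-seq of paired-end fragments. The pipeline rests on four
measurable signatures of a point-like centromeric particle:

1. **Localized enrichment.** Fragments immunoprecipitated with a
   centromeric-histone antibody pile up in narrow peaks over an
   input-subtracted background.
2. **Sub-nucleosomal protection.** Fragments that cross a centromere
   site are shorter (roughly 60–120 bp) than the ~166 bp
   nucleosome-plus-linker fragments that cross ordinary dyads.
3. **Positioned flanking nucleosomes.** Well-phased nucleosomes sit at
   roughly ±150 bp from the site midpoint.
4. **MNase hypersensitivity.** With increasing digestion time, the
   centromeric particle is lost faster than bulk nucleosomes, so the
   occupancy ratio relative to the lightest digest falls more steeply
   at sites than at flanking nucleosomes.

The package provides the primitives for each step (binning,
normalization, subtraction, threshold peak calling, crossing-size
distributions, occupancy kinetics, and overlap statistics), a seeded
synthetic-data generator with planted ground truth to exercise them end
to end, and `tidy()`/`glance()`/`autoplot()` methods for inspection.

## Track construction

Fragments are loaded with `read_fragments()` (BEDPE, BED, or paired
alignments via Rsamtools), filtered to a length window (default
26–500 bp), and binned with `bin_fragments()` at 10 bp resolution.
Two counting modes exist:

* `"midpoint"` assigns each fragment once, to the bin containing
  `floor((start + end) / 2)`. This estimates *dyad density* and is used
  for peak calling and for locating phased flanking nucleosomes, where
  a per-particle point estimate is wanted.
* `"coverage"` adds one to every bin the fragment overlaps. This
  estimates *occupancy* and is used for footprint-width measurements.

`normalize_track()` rescales counts so that the genome-wide mean equals
the bin size, i.e. the track sums to the number of unmasked bases.
Tracks from different sequencing depths are then directly comparable,
and a value of 10 in a 10 bp bin means "exactly average". Masked bins
(`mask_regions()`) are `NA`, are excluded from all statistics, and
propagate through `subtract_track()` and `log2_ratio_track()`.

## Peak calling

`threshold_from_stats()` computes mean + *k*·SD of the ChIP-minus-input
difference track over unmasked bins, with *k* = 7 by default. The SD is
the population SD (divisor *n*), matching the definition of a moment of
the empirical bin distribution rather than an estimator for a sampled
one; at millions of bins the two are numerically indistinguishable.

`call_peaks()` accepts one track per replicate. Runs of consecutive
bins at or above threshold are found per replicate, the per-replicate
runs are unioned, and each merged region records its replicate
`support`; `min_support = 1` (the default) keeps regions exceeding the
threshold in at least one replicate. We chose the union-with-support
rule over intersection because a site that narrowly misses threshold in
one replicate is still recoverable, while `support` lets a stricter
caller ask for `min_support = 2` without re-running. The summit is the
center of the bin with the maximal replicate-mean value (leftmost on
ties, so results are deterministic).

`peak_windows()` expands summits to fixed windows (default 200 bp),
clips at chromosome ends, and records the union coverage of the
windows, which is the denominator for density and fold-enrichment
arithmetic (`fold_enrichment()` scales to counts per 10 Mb).

## Fragment-size geometry

`crossing_size_distribution()` counts, for each anchor, the lengths of
fragments whose half-open span `start <= pos < end` contains the
anchor; a fragment crossing two anchors contributes to both. The
half-open convention matches the 0-based BED coordinate system, so a
fragment of length L crosses exactly L integer positions.

`half_height_width()` measures a footprint width on an averaged
profile: the baseline is the median of the outer 10% of positions on
each side, the half height is midway between baseline and maximum, and
the crossings are linearly interpolated moving outward from the peak.
If a side never falls below half height the profile is reported as
unbounded rather than silently truncated.

Two resolution choices matter here and are deliberate:

* Footprint widths are measured on a **2 bp coverage** track. A 10 bp
  bin convolves the profile with a 10 bp box and widens an 80 bp
  footprint by roughly one bin; at 2 bp the bias is negligible
  relative to the ±10 bp tolerance we quote.
* Flanking nucleosomes are located with
  `locate_flanking_nucleosomes()` on a **midpoint-counted (dyad
  density) track of nucleosomal fragments** (141–500 bp, from
  `partition_by_size()`). Coverage profiles of positioned nucleosomes
  are flat-topped plateaus ~150 bp wide, so their local maxima are
  ill-defined; dyad density has a sharp mode at the nucleosome center.
  Ties are broken toward the anchor.

## Digestion kinetics

`occupancy_at_features()` averages the per-anchor window means of a
normalized track. `sensitivity_series()` divides the occupancy at each
digestion time by the occupancy at the first (lightest) time point, so
every series starts at 1 and the common sequencing-depth normalization
cancels. Under an exponential survival model `exp(-lambda * t)`,
`fit_decay_rate()` recovers lambda as the negative slope of
`log(ratio)` against minutes. A hypersensitive particle shows a larger
lambda than bulk chromatin.

## Overlap statistics

`overlap_count()` supports two rules: `summit_in_interval` (a point
summit falls inside a half-open interval) and `any_overlap`.
`hypergeometric_overlap()` computes the upper-tail probability of
observing at least k overlaps via `stats::phyper()` in log space, so
extreme tails (below 1e-250) do not underflow prematurely.
`permutation_overlap_test()` re-places the summits uniformly on the
unmasked portion of each chromosome (preserving per-chromosome counts)
and reports the add-one permutation p-value
`(1 + #{perm >= obs}) / (1 + n_perm)`, which is valid (super-uniform
under the null) for any number of permutations. The RNG state is saved
and restored, so calling the test does not perturb the caller's
stream.

## The synthetic generator

`scenario_config()` + `simulate_scenario()` generate paired-end
fragment sets with planted truth for three tracks (ChIP, input, and an
insoluble/pellet fraction), several digestion time points, replicates,
and an optional depletion condition. All randomness derives from
`set.seed(config$seed)`, so a configuration is a complete recipe for
its dataset; `write_scenario()` emits BEDPE, chrom.sizes, truth BED
files, and `truth.json`.

Per (track, time, replicate) the generator draws four Poisson
components:

* **background** nucleosomes uniform on the chromosome,
* **flanking** nucleosomes at planted dyads (site ±150 bp, with
  ~10 bp placement jitter in the truth itself),
* **site** particles with sub-nucleosomal protection drawn uniformly
  from 60–100 bp per site,
* **domain** fragments, a milder enrichment over broad intervals,
  emulating the extended domains within which sites sit.

Fragment length is protection + linker, where the linker shrinks with
digestion time as `linker * exp(-lambda_nuc * t)`; site and domain
components decay with `lambda_cen = 2 * lambda_nuc` (hypersensitive)
and the insoluble track decays more slowly (protected). Lengths get
N(0, 8) jitter, centers N(0, 6), and everything is clamped to the
21–500 bp window and chromosome bounds. A depletion condition scales
site-derived ChIP fragments by `knl2_factor`. A set of "HOT" intervals
(half at sites, half decoys) supports overlap-statistics exercises.

What the generator **emulates**: localized sub-nucleosomal enrichment
over a domain background, phased flanking nucleosomes, differential
MNase sensitivity between site particles, bulk nucleosomes, and an
insoluble fraction, replicate structure, and depletion. What it does
**not** emulate: sequence-dependent MNase bias, mappability and copy
number artifacts, chromatin higher-order structure, PCR duplicates, or
read-level errors — the generator produces fragments, not reads. It is
a test harness for the analysis arithmetic, not a simulator of an
experiment.

Default problem sizes (one 5 Mb chromosome, 50 sites, ~7 M fragments
across 28 fragment sets, ~7 s to simulate) are chosen so that a full
simulate-analyze round trip runs in seconds on a laptop while keeping
Poisson noise small enough that planted effects are measured, not
guessed. They are this package's own testing choices, not estimates of
any particular genome.

```{r example, fig.width = 6, fig.height = 3}
sim <- simulate_scenario(scenario_config(
  seed = 11, chrom_length = 1e6, n_sites = 10, timepoints = c(1, 2)))
gb <- sim$genome
d <- subtract_track(
  normalize_track(bin_fragments(scenario_fragments(sim, "chip", 2, 1), gb)),
  normalize_track(bin_fragments(scenario_fragments(sim, "input", 2, 1), gb)))
pk <- call_peaks(d, threshold = threshold_from_stats(d))
nrow(pk)
autoplot(d) +
  geom_vline(xintercept = sim$truth$sites$pos, linetype = 3, colour = "red")
```

## Limitations

* The peak caller is a global-threshold method; it assumes the
  difference track is stationary after input subtraction and will
  misbehave on strong unmasked copy-number variation. Use
  `mask_regions()` for known artifacts.
* `fit_decay_rate()` fits a single exponential; mixtures of protected
  and sensitive particles at the same anchors will bias lambda toward
  the slower component at late time points. Keep backgrounds low or
  time courses short when absolute rates matter.
* The permutation test randomizes positions uniformly per chromosome;
  it does not preserve local clustering of the query set, so its null
  is "random placement", not "random shift".
* Half-height widths need the averaged profile to return to baseline
  within the matrix window; pick `window` at least a few footprint
  widths wide.
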