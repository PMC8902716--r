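#' Preset simulation designs
#'
#' Canonical study conditions for each scan, used throughout the test suite:
#' \describe{
#'   \item{`sim_config_sdr()`}{a dioecious natural population (60 samples,
#'     1:1 sex ratio) on 3 x 10 Mb with a 2-Mb SDR on chr1 (4-6 Mb); pairs
#'     with [simulate_f1_cross()] for the co-segregation track.}
#'   \item{`sim_config_sweep()`}{wild (15) and cultivated (30) groups; the
#'     cultivated group carries a 1-Mb sweep on chr2 (4-5 Mb) at the given
#'     strength.}
#'   \item{`sim_config_introgression()`}{a four-taxon design. `mode="dstat"`
#'     is the genome-wide Patterson's D configuration: two conspecific
#'     subgroups (12 each, F = 0.15), a strongly diverged donor species
#'     (10, F = 0.9), a small outgroup panel, and a 1-Mb admixture region
#'     spanning 10\% of a 10-Mb genome at standard density.
#'     `mode="scan"` is the fine-mapping configuration for the 1-kb fd_M
#'     scan: a dense variant panel (40 sites/kb, so each 1-kb window holds
#'     tens of informative sites), large conspecific sister panels (25
#'     each, F = 0.02), a strongly diverged donor species (10, F = 0.9),
#'     and a 100-kb admixture region.}
#' }
#'
#' @param seed integer seed.
#' @param sweep_strength sweep intensity (fraction of sites driven to
#'   near-fixation).
#' @param gamma per-haplotype donor-copy probability.
#' @param mode `"dstat"` or `"scan"` (see above).
#' @param sdr include the SDR truth region? (`FALSE` for null calibration).
#' @param sweep include the sweep truth region?
#' @param introgression include the admixture truth region? (`gamma = 0`
#'   keeps the region labeled but copies nothing, the null condition).
#' @return A [sim_config()].
#' @name sim_presets
NULL

#' @rdname sim_presets
#' @export
sim_config_sdr <- function(seed, sdr = TRUE) {
  sim_config(
    populations = data.frame(name = "pop1", size = 60, sex_ratio = 0.5,
                             fst = 0.1, stringsAsFactors = FALSE),
    chrom_lengths = c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7),
    snp_per_kb = 2,
    sdr_region = if (sdr) list(chrom = "chr1", start = 4e6, end = 6e6),
    seed = seed)
}

#' @rdname sim_presets
#' @export
sim_config_sweep <- function(seed, sweep_strength = 0.95, sweep = TRUE) {
  sim_config(
    populations = data.frame(name = c("wild", "cultivated"),
                             size = c(15, 30), sex_ratio = 0.5,
                             fst = c(0.15, 0.25), stringsAsFactors = FALSE),
    chrom_lengths = c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7),
    snp_per_kb = 2,
    sdr_region = NULL,
    sweep_region = if (sweep) list(chrom = "chr2", start = 4e6, end = 5e6),
    sweep_strength = sweep_strength,
    cultivated = "cultivated",
    seed = seed)
}

#' @rdname sim_presets
#' @export
sim_config_introgression <- function(seed, gamma = 0.5,
                                     mode = c("scan", "dstat"),
                                     introgression = TRUE) {
  mode <- match.arg(mode)
  if (mode == "dstat") {
    sim_config(
      populations = data.frame(name = c("P1", "P2", "P3", "OUT"),
                               size = c(12, 12, 10, 4), sex_ratio = 0.5,
                               fst = c(0.15, 0.15, 0.9, 0.3),
                               stringsAsFactors = FALSE),
      chrom_lengths = c(chr1 = 1e7), snp_per_kb = 8,
      sdr_region = NULL,
      introgression_region = if (introgression) {
        list(chrom = "chr1", start = 4e6, end = 5e6)
      },
      quartet = list(P1 = "P1", P2 = "P2", P3 = "P3", O = "OUT"),
      gamma = gamma, seed = seed)
  } else {
    sim_config(
      populations = data.frame(name = c("P1", "P2", "P3", "OUT"),
                               size = c(25, 25, 10, 4), sex_ratio = 0.5,
                               fst = c(0.02, 0.02, 0.9, 0.3),
                               stringsAsFactors = FALSE),
      chrom_lengths = c(chr1 = 1e7), snp_per_kb = 40,
      sdr_region = NULL,
      introgression_region = if (introgression) {
        list(chrom = "chr1", start = 2e6, end = 2.1e6)
      },
      quartet = list(P1 = "P1", P2 = "P2", P3 = "P3", O = "OUT"),
      gamma = gamma, seed = seed)
  }
}

#' Quartet specification for a simulated four-taxon dataset
#' @param sim result of [simulate_population()] under an introgression
#'   preset.
#' @return A [quartet_spec()].
#' @export
sim_quartet <- function(sim) {
  quartet_spec(sheet_samples(sim$sheet, group = "P1"),
               sheet_samples(sim$sheet, group = "P2"),
               sheet_samples(sim$sheet, group = "P3"),
               sheet_samples(sim$sheet, group = "OUT"))
}
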