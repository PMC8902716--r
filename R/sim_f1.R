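#' Simulate an F1 cross segregating sex
#'
#' Builds four founder haplotypes — two maternal X's, and a paternal X and Y
#' — from population allele frequencies, then draws offspring that inherit
#' one haplotype from each parent with free recombination outside the SDR
#' and none inside it. Offspring carrying the paternal Y block are male.
#' Inside the SDR, Y-linked marker sites put the derived allele on the Y
#' haplotype only, so the father is heterozygous and carrier status equals
#' sex in every offspring; all such father-heterozygous Y-diagnostic sites
#' (markers, plus background sites that happen to be Y-diagnostic) are
#' labeled `coseg_snp` in the truth set.
#'
#' @param cfg a [sim_config()] with `sdr_region` set.
#' @param n_offspring number of F1 individuals (>= 2).
#' @param out_dir optional output directory (see [write_simulation()]).
#' @return A list with `sites`, `sheet`, `truth` (regions + `coseg_sites`),
#'   `chrom_lengths`, and `paths` when written.
#' @export
simulate_f1_cross <- function(cfg, n_offspring = 80, out_dir = NULL) {
  if (is.null(cfg$sdr_region)) stop("simulate_f1_cross: sdr_region must be set")
  if (n_offspring < 2) stop("simulate_f1_cross: n_offspring must be >= 2")
  set.seed(cfg$seed + 1L)  # distinct stream from the population draw
  r <- cfg$sdr_region

  chrom <- character(0); pos <- integer(0)
  for (chr in names(cfg$chrom_lengths)) {
    len <- cfg$chrom_lengths[[chr]]
    n_bg <- round(len / 1000 * cfg$snp_per_kb)
    p <- sort(sample.int(len, n_bg))
    chrom <- c(chrom, rep(chr, n_bg)); pos <- c(pos, p)
  }
  # Y-linked marker sites
  n_y <- round((r$end - r$start) / 1000 * cfg$y_marker_density)
  ypos <- r$start + sort(sample.int(r$end - r$start, n_y))
  ypos <- setdiff(ypos, pos[chrom == r$chrom])
  ord <- order(c(chrom, rep(r$chrom, length(ypos))), c(pos, ypos))
  is_marker <- c(rep(FALSE, length(pos)), rep(TRUE, length(ypos)))[ord]
  chrom <- c(chrom, rep(r$chrom, length(ypos)))[ord]
  pos <- c(pos, ypos)[ord]
  S <- length(pos)

  # founder haplotypes from a single panmictic frequency draw
  x <- rneutral_freq(S, n_offspring + 2)
  hap <- matrix(0L, S, 4, dimnames = list(NULL, c("m1", "m2", "fX", "fY")))
  for (k in 1:4) hap[, k] <- stats::rbinom(S, 1, x)
  sdr <- in_region(chrom, pos, r)
  # the non-recombining Y block diverges only at its marker sites; elsewhere
  # it carries the same allele as the father's X
  hap[sdr, "fY"] <- hap[sdr, "fX"]
  hap[is_marker, ] <- 0L
  hap[is_marker, "fY"] <- 1L
  ids <- c("mother", "father", sprintf("F1_%03d", seq_len(n_offspring)))
  geno <- matrix(NA_integer_, S, n_offspring + 2, dimnames = list(NULL, ids))
  geno[, "mother"] <- hap[, "m1"] + hap[, "m2"]
  geno[, "father"] <- hap[, "fX"] + hap[, "fY"]
  kid_sex <- character(n_offspring)
  for (j in seq_len(n_offspring)) {
    pick_m <- stats::rbinom(S, 1, 0.5)          # 0 -> m1, 1 -> m2
    pick_p <- stats::rbinom(S, 1, 0.5)          # 0 -> fX, 1 -> fY
    pick_m[sdr] <- stats::rbinom(1, 1, 0.5)     # no recombination inside SDR
    pick_p[sdr] <- stats::rbinom(1, 1, 0.5)
    gm <- ifelse(pick_m == 0, hap[, "m1"], hap[, "m2"])
    gp <- ifelse(pick_p == 0, hap[, "fX"], hap[, "fY"])
    geno[, ids[j + 2]] <- gm + gp
    kid_sex[j] <- if (pick_p[sdr][1] == 1) "M" else "F"
  }
  if (!any(sdr)) kid_sex[] <- sample(c("M", "F"), n_offspring, replace = TRUE)

  sheet <- sample_sheet(ids, group = "cross",
                        sex = c("F", "M", kid_sex),
                        role = c("parent_female", "parent_male",
                                 rep("F1", n_offspring)))
  ra <- sim_ref_alt(S)
  sites <- site_table(chrom, pos, ra$ref, ra$alt, geno)

  # truth: father-heterozygous Y-diagnostic sites within the SDR
  ydiag <- sdr & hap[, "fX"] != hap[, "fY"] &
    hap[, "m1"] == hap[, "m2"] & hap[, "m1"] != hap[, "fY"]
  coseg_sites <- data.frame(chrom = chrom[ydiag], pos = pos[ydiag],
                            stringsAsFactors = FALSE)
  truth <- list(regions = truth_regions(cfg), coseg_sites = coseg_sites)
  out <- list(sites = sites, sheet = sheet, truth = truth,
              chrom_lengths = cfg$chrom_lengths)
  if (!is.null(out_dir)) out$paths <- write_simulation(out, out_dir)
  out
}
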