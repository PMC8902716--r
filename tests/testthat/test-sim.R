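# smaller genome than the preset defaults to keep unit tests fast
small_cfg <- function(seed, ...) {
  sim_config(chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
             sdr_region = list(chrom = "chr1", start = 3e5, end = 6e5),
             seed = seed, ...)
}

test_that("identical configuration and seed give byte-identical VCFs", {
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(simulate_population(small_cfg(99))$sites, f1)
  write_vcf(simulate_population(small_cfg(99))$sites, f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed changes the data
  f3 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(simulate_population(small_cfg(100))$sites, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("simulated output parses under read_vcf with zero skips", {
  sim <- simulate_population(small_cfg(3))
  d <- withr::local_tempdir()
  paths <- write_simulation(sim, d)
  sheet <- read_sample_sheet(paths$sheet)
  st <- read_vcf(paths$vcf, sheet, max_missing = 1, min_maf = 0)
  expect_equal(attr(st, "n_skipped"), 0)
  expect_equal(n_sites(st), n_sites(sim$sites))
  truth <- read_bed(paths$truth_bed)
  expect_equal(truth$name, "sdr")
})

test_that("Y-marker sites are heterozygous in males and absent in females", {
  sim <- simulate_population(small_cfg(5))
  ym <- sim$truth$y_markers
  expect_gt(nrow(ym), 0)
  idx <- match(paste(ym$chrom, ym$pos), paste(sim$sites$chrom, sim$sites$pos))
  females <- sheet_samples(sim$sheet, sex = "F")
  males <- sheet_samples(sim$sheet, sex = "M")
  expect_true(all(sim$sites$geno[idx, females] == 0))
  expect_true(all(sim$sites$geno[idx, males] == 1))
  # every labeled site lies inside the labeled region
  expect_true(all(ym$pos - 1 >= 3e5 & ym$pos - 1 < 6e5))
})

test_that("heterozygosity tracks the simulated diversity parameter", {
  # lower Balding-Nichols F -> populations closer to the ancestral frequency
  # -> higher expected heterozygosity
  fs <- c(0.05, 0.15, 0.3, 0.5, 0.7)
  het <- vapply(seq_along(fs), function(i) {
    cfg <- sim_config(populations = data.frame(name = "p", size = 20,
                                               sex_ratio = 0.5, fst = fs[i]),
                      chrom_lengths = c(chr1 = 5e5), sdr_region = NULL,
                      seed = 400 + i)
    sim <- simulate_population(cfg)
    mean(het_rate(sim$sites))
  }, numeric(1))
  expect_gt(cor(-fs, het, method = "spearman"), 0.9)
})

test_that("F1 cross segregates sex with the Y haplotype", {
  cfg <- small_cfg(7)
  f1 <- simulate_f1_cross(cfg, n_offspring = 60)
  cs <- f1$truth$coseg_sites
  expect_gt(nrow(cs), 0)
  idx <- match(paste(cs$chrom, cs$pos), paste(f1$sites$chrom, f1$sites$pos))
  kids <- sheet_samples(f1$sheet, role = "F1")
  kid_male <- f1$sheet$sex[match(kids, f1$sheet$sample_id)] == "M"
  fa <- as.vector(f1$sites$geno[idx, sheet_samples(f1$sheet, role = "parent_male")])
  mo <- as.vector(f1$sites$geno[idx, sheet_samples(f1$sheet, role = "parent_female")])
  expect_true(all(fa == 1))
  Gk <- f1$sites$geno[idx, kids, drop = FALSE]
  y_allele_carried <- ifelse(rep(mo, ncol(Gk)) == 0, Gk >= 1, Gk <= 1)
  expect_true(all(y_allele_carried == rep(kid_male, each = nrow(Gk))))
  expect_error(simulate_f1_cross(cfg, 1), "n_offspring")
  expect_error(simulate_f1_cross(sim_config(chrom_lengths = c(chr1 = 1e6),
                                            sdr_region = NULL, seed = 1)),
               "sdr_region")
})

test_that("F1 sex ratio is binomial around 1:1", {
  f1 <- simulate_f1_cross(small_cfg(8), n_offspring = 200)
  n_m <- sum(f1$sheet$sex[f1$sheet$role == "F1"] == "M")
  ci <- qbinom(c(0.0005, 0.9995), 200, 0.5)
  expect_gte(n_m, ci[1])
  expect_lte(n_m, ci[2])
})

test_that("flagged co-segregating sites equal the truth labels exactly", {
  cfg <- small_cfg(9)
  f1 <- simulate_f1_cross(cfg, n_offspring = 80)
  sim <- simulate_population(cfg)
  res <- flag_coseg_and_contigs(f1$sites, f1$sheet, sim$contigs)
  flagged <- paste(f1$sites$chrom, f1$sites$pos)[res$coseg]
  labeled <- paste(f1$truth$coseg_sites$chrom, f1$truth$coseg_sites$pos)
  expect_setequal(flagged, labeled)
})

test_that("a markerless SDR yields no co-segregation labels", {
  cfg <- small_cfg(10, y_marker_density = 0)
  f1 <- simulate_f1_cross(cfg, n_offspring = 20)
  expect_equal(nrow(f1$truth$coseg_sites), 0)
})

test_that("overlapping truth regions are rejected", {
  expect_error(sim_config(chrom_lengths = c(chr1 = 1e6),
                          sdr_region = list(chrom = "chr1", start = 0, end = 5e5),
                          sweep_region = list(chrom = "chr1", start = 4e5, end = 6e5),
                          seed = 1),
               "overlapping truth regions")
  expect_error(sim_config(chrom_lengths = c(chr1 = 1e6),
                          sdr_region = list(chrom = "chr1", start = 0, end = 2e6),
                          seed = 1),
               "bounds")
  expect_error(sim_config(seed = NULL), "seed")
})

test_that("sequence-pair simulator hits divergence targets", {
  # zero targets give identical pairs
  p0 <- simulate_sequence_pairs(2, target_ks = 0, target_ka = 0,
                                n_codons = 100, seed = 1)
  expect_identical(p0[[1]][1], p0[[1]][2])
  r0 <- ng86_kaks(p0[[1]][1], p0[[1]][2])
  expect_equal(r0$Ks, 0)
  expect_equal(r0$Ka, 0)
  # Ks recovery within 10% at the study's stratum-1 divergence
  pairs <- simulate_sequence_pairs(20, target_ks = 0.011, n_codons = 5000,
                                   seed = 2)
  ks <- vapply(pairs, function(p) ng86_kaks(p[1], p[2])$Ks, numeric(1))
  expect_lt(abs(mean(ks) - 0.011) / 0.011, 0.10)
  # K2P recovery within 5% on a 10-kb LTR-style pair set
  ltr <- simulate_ltr_pairs(10, target_k = 0.17, length_bp = 1e4, seed = 3)
  kk <- vapply(ltr, function(p) k2p_distance(p[1], p[2])$K, numeric(1))
  expect_lt(abs(mean(kk) - 0.17) / 0.17, 0.05)
  expect_error(simulate_ltr_pairs(1, target_k = -1), "non-negative")
})
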