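test_that("NG86 matches hand-verifiable anchors", {
  s1 <- "ATGAAAGGGCCCTTTGAA"
  s2 <- "ATGAAGGGGACCTTTGAA"  # one synonymous (AAA>AAG), one nonsyn (CCC>ACC)
  r <- ng86_kaks(s1, s2)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 1)
  # frozen values, cross-checked against an independent NG86 implementation
  expect_equal(r$Ka, 0.06981781729950898, tolerance = 1e-12)
  expect_equal(r$Ks, 0.4408399986765892, tolerance = 1e-12)
  o <- oracle_ng86(s1, s2)
  expect_equal(r$Ka, o$Ka, tolerance = 1e-12)
  expect_equal(r$Ks, o$Ks, tolerance = 1e-12)

  ident <- ng86_kaks(s1, s1)
  expect_equal(ident$Ka, 0)
  expect_equal(ident$Ks, 0)
  expect_true(is.na(ident$ka_ks))
  expect_error(ng86_kaks("ATGA", "ATGA"), "divisible")
  expect_error(ng86_kaks("ATGTAAAAA", "ATGTAAAAA"), "stop")
})

test_that("NG86 equals the pathway-enumeration oracle on random pairs", {
  pairs <- simulate_sequence_pairs(3, target_ks = 0.3, target_ka = 0.15,
                                   n_codons = 40, seed = 8)
  for (p in pairs) {
    r <- ng86_kaks(p[1], p[2])
    o <- oracle_ng86(p[1], p[2])
    expect_equal(r$Ka, o$Ka, tolerance = 1e-12)
    expect_equal(r$Ks, o$Ks, tolerance = 1e-12)
    # symmetry under argument swap
    rs <- ng86_kaks(p[2], p[1])
    expect_equal(rs$Ka, r$Ka, tolerance = 1e-12)
    expect_equal(rs$Ks, r$Ks, tolerance = 1e-12)
  }
  # invariance under codon-block shuffling of the aligned pair
  p <- pairs[[1]]
  idx <- sample(40)
  shuffle <- function(s) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    paste(cods[idx], collapse = "")
  }
  r0 <- ng86_kaks(p[1], p[2])
  r1 <- ng86_kaks(shuffle(p[1]), shuffle(p[2]))
  expect_equal(r1$Ks, r0$Ks, tolerance = 1e-12)
  expect_equal(r1$Ka, r0$Ka, tolerance = 1e-12)
})

test_that("NG86 flags saturation instead of extrapolating", {
  # a pair built to exceed the 3/4 synonymous-proportion ceiling:
  # third positions of 4-fold codons fully scrambled is unreachable, so use
  # a tiny pair whose only difference pattern saturates ps
  s1 <- paste(rep("GGT", 8), collapse = "")
  s2 <- paste(rep(c("GGA", "GGC", "GGG"), length.out = 8), collapse = "")
  expect_error(ng86_kaks(s1, s2), "saturation")
})

test_that("K2P distance matches the closed form and ape's K80", {
  r <- k2p_distance("AAAAACCCCCGGGGGTTTTT", "GAAAACCCCCGGGGGTTTTC")
  expect_equal(r$P, 0.10)
  expect_equal(r$Q, 0)
  # P = 0.1, Q = 0.05 closed-form anchor
  a <- paste(rep("A", 20), collapse = "")
  b <- paste(c(rep("G", 2), rep("C", 1), rep("A", 17)), collapse = "")
  rb <- k2p_distance(a, b)
  expect_equal(rb$P, 0.1)
  expect_equal(rb$Q, 0.05)
  expect_equal(rb$K, -0.5 * log(1 - 2 * 0.1 - 0.05) - 0.25 * log(1 - 2 * 0.05),
               tolerance = 1e-12)
  expect_equal(rb$K, 0.17018, tolerance = 1e-4)
  # random sequences vs ape::dist.dna(model = "K80")
  skip_if_not_installed("ape")
  set.seed(19)
  for (i in 1:3) {
    x <- sample(c("a", "c", "g", "t"), 600, replace = TRUE)
    y <- x
    mut <- runif(600) < 0.1
    y[mut] <- sample(c("a", "c", "g", "t"), sum(mut), replace = TRUE)
    bin <- ape::as.DNAbin(rbind(x, y))
    expect_equal(k2p_distance(paste(x, collapse = ""),
                              paste(y, collapse = ""))$K,
                 as.numeric(ape::dist.dna(bin, model = "K80")),
                 tolerance = 1e-12)
  }
  expect_error(k2p_distance("ACGT", "ACG"), "length")
})

test_that("divergence time follows T = K / 2r", {
  expect_equal(divergence_time(0.0056, 2.8e-9), 1e6)
  expect_equal(divergence_time(0), 0)
  expect_equal(divergence_time(0.01, 5.6e-9), divergence_time(0.01, 2.8e-9) / 2)
  expect_error(divergence_time(-0.1), "negative")
  expect_error(divergence_time(0.1, 0), "positive")
})

test_that("date_pairs produces per-pair ages in both modes", {
  pairs <- simulate_sequence_pairs(4, target_ks = 0.0111, n_codons = 1500,
                                   seed = 12)
  dated <- date_pairs(pairs, mode = "gene")
  expect_equal(nrow(dated), 4)
  expect_equal(dated$T_years, dated$Ks / (2 * 2.8e-9))
  expect_equal(attr(dated, "method"), "NG86")
  ltr <- simulate_ltr_pairs(3, target_k = 0.05, length_bp = 5000, seed = 13)
  dl <- date_pairs(ltr, mode = "ltr")
  expect_equal(dl$T_years, dl$K / (2 * 2.8e-9))
  # FASTA round trip preserves pairing
  f <- withr::local_tempfile(fileext = ".fa")
  write_pair_fasta(pairs, f)
  back <- read_pair_fasta(f)
  expect_equal(names(back), names(pairs))
  expect_equal(unname(unlist(back)), unname(unlist(pairs)))
})

test_that("stratum summaries separate shifted strata by permutation test", {
  pairs1 <- simulate_sequence_pairs(8, target_ks = 0.011, n_codons = 1200,
                                    seed = 14)
  dated <- date_pairs(pairs1)
  # identical age lists -> p near 1
  ids2 <- c(names(pairs1), paste0(names(pairs1), "_b"))
  assign_same <- data.frame(pair_id = ids2,
                            stratum = rep(c("s1", "s2"), each = 8))
  dated2 <- rbind(dated, dated)
  dated2$pair_id <- ids2
  set.seed(1)
  same <- stratum_summary(dated2, assign_same, n_permutations = 2000)
  expect_equal(same$comparisons$p_value, 1, tolerance = 0.01)
  expect_equal(same$summary$n, c(8, 8))
  # strata shifted far apart -> p below 0.001
  shifted <- dated
  shifted$pair_id <- paste0(shifted$pair_id, "_b")
  shifted$T_years <- shifted$T_years + 100 * sd(dated$T_years)
  both <- rbind(dated, shifted)
  assign2 <- data.frame(pair_id = both$pair_id,
                        stratum = rep(c("s1", "s2"), each = 8))
  set.seed(2)
  res <- stratum_summary(both, assign2, n_permutations = 5000)
  expect_lt(res$comparisons$p_value, 0.001)
})
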