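test_that("per-site pi matches haplotype-pair enumeration", {
  expect_equal(site_pi(2, 4), oracle_site_pi(2, 4))
  expect_equal(site_pi(2, 4), 2 / 3)
  expect_equal(site_pi(0, 10), 0)
  expect_equal(site_pi(10, 10), 0)
  expect_true(is.na(site_pi(1, 1)))
  for (n in c(4, 7, 12)) for (c1 in 0:n) {
    expect_equal(site_pi(c1, n), oracle_site_pi(c1, n), tolerance = 1e-12)
  }
})

test_that("het_rate counts heterozygous fraction per sample", {
  G <- matrix(c(1, 0, 2, 1, 1, NA, 0, 0, 0, 2), nrow = 5,
              dimnames = list(NULL, c("a", "b")))
  st <- site_table(rep("chr1", 5), 1:5, rep("A", 5), rep("G", 5), G)
  hr <- het_rate(st)
  expect_equal(unname(hr["a"]), 3 / 5)
  expect_equal(unname(hr["b"]), 0 / 4)
})

test_that("folded SFS matches the min(c, n-c) tally", {
  G <- matrix(c(1, 0, 0, 0,   1, 0, 0, 0,   1, 1, 0, 0), nrow = 3,
              byrow = TRUE, dimnames = list(NULL, sprintf("s%d", 1:4)))
  st <- site_table(rep("chr1", 3), 1:3, rep("A", 3), rep("G", 3), G)
  sfs <- folded_sfs(st, st$samples)
  expect_equal(unname(sfs), c(2, 1, 0, 0))  # n = 8 alleles -> classes 1..4
  # random full-call fixture vs oracle
  st2 <- random_site_table(60, 6, seed = 11, miss_rate = 0)
  expect_equal(unname(folded_sfs(st2, st2$samples)),
               oracle_folded_sfs(st2$geno))
  # monomorphic sites excluded
  Gm <- matrix(rep(2L, 8), nrow = 2, dimnames = list(NULL, sprintf("s%d", 1:4)))
  stm <- site_table(rep("chr1", 2), 1:2, rep("A", 2), rep("G", 2), Gm)
  expect_equal(sum(folded_sfs(stm, stm$samples)), 0)
})

test_that("sex association chi-square matches the closed form and chisq.test", {
  # 44 males homozygous alt (88 alt/0 ref alleles), 26 females all ref
  G <- rbind(c(rep(2L, 44), rep(0L, 26)))
  colnames(G) <- sprintf("s%02d", 1:70)
  st <- site_table("chr1", 1000L, "A", "G", G)
  sheet <- sample_sheet(colnames(G), "pop",
                        c(rep("M", 44), rep("F", 26)))
  res <- sex_association_scan(st, sheet)
  expect_equal(res$chisq, 140)  # table total N for perfect separation
  expect_gt(res$assoc_score, 31)
  expect_lt(res$assoc_score, 33)
  ct <- suppressWarnings(
    chisq.test(matrix(c(88, 0, 0, 52), 2), correct = FALSE))
  expect_equal(res$chisq, unname(ct$statistic), tolerance = 1e-12)

  # equal frequencies and monomorphic sites score zero
  G2 <- rbind(c(rep(1L, 6), rep(1L, 6)), rep(0L, 12))
  colnames(G2) <- sprintf("t%02d", 1:12)
  st2 <- site_table(rep("chr1", 2), c(10L, 20L), rep("A", 2), rep("G", 2), G2)
  sheet2 <- sample_sheet(colnames(G2), "pop", rep(c("M", "F"), each = 6))
  res2 <- sex_association_scan(st2, sheet2)
  expect_equal(res2$assoc_score, c(0, 0))
  expect_error(sex_association_scan(st2, sample_sheet(colnames(G2), "pop",
                                                      rep("U", 12))),
               "each sex")
})

test_that("association scan matches chisq.test on random two-sex fixtures", {
  st <- random_site_table(50, 16, seed = 21)
  sheet <- fixture_sheet(st$samples, 8)
  res <- sex_association_scan(st, sheet)
  males <- sheet$sample_id[sheet$sex == "M"]
  females <- sheet$sample_id[sheet$sex == "F"]
  for (i in seq_len(50)) {
    gm <- st$geno[i, males]; gf <- st$geno[i, females]
    tab <- matrix(c(sum(gm, na.rm = TRUE), 2 * sum(!is.na(gm)) - sum(gm, na.rm = TRUE),
                    sum(gf, na.rm = TRUE), 2 * sum(!is.na(gf)) - sum(gf, na.rm = TRUE)),
                  2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      expect_equal(res$chisq[i], 0)
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      expect_equal(res$chisq[i], unname(ct$statistic), tolerance = 1e-12)
    }
  }
})

test_that("male-specific flags follow carrier and call-rate thresholds", {
  sheet <- sample_sheet(sprintf("s%02d", 1:20), "pop",
                        c(rep("M", 10), rep("F", 10)))
  mk <- function(males, females) {
    G <- rbind(c(males, females))
    colnames(G) <- sheet$sample_id
    site_table("chr1", 1L, "A", "G", G)
  }
  allcall <- rep(0L, 10)
  # het in all males, absent in females -> flagged
  expect_true(flag_male_specific(mk(rep(1L, 10), allcall), sheet))
  # one female carrier kills the flag
  expect_false(flag_male_specific(mk(rep(1L, 10), c(1L, allcall[-1])), sheet))
  # 9/10 male carriers: exactly at the 0.90 boundary -> flagged
  expect_true(flag_male_specific(mk(c(rep(1L, 9), 0L), allcall), sheet))
  # 8/10 male carriers -> below threshold
  expect_false(flag_male_specific(mk(c(rep(1L, 8), 0L, 0L), allcall), sheet))
  # call-rate gate: 7/10 females genotyped < 0.80
  expect_false(flag_male_specific(mk(rep(1L, 10),
                                     c(rep(NA, 3), rep(0L, 7))), sheet))
})

test_that("co-segregation requires father-het sites and >= 4-SNP contigs", {
  kids <- sprintf("k%02d", 1:10)
  sheet <- sample_sheet(c("mo", "fa", kids), "cross",
                        c("F", "M", rep(c("M", "F"), 5)),
                        role = c("parent_female", "parent_male", rep("F1", 10)))
  kid_male <- rep(c(TRUE, FALSE), 5)
  # 5 perfectly co-segregating sites on tig1, 3 on tig2, 1 broken site
  n <- 9
  G <- matrix(0L, n, 12, dimnames = list(NULL, c("mo", "fa", kids)))
  G[, "fa"] <- 1L
  for (i in 1:8) G[i, kids] <- ifelse(kid_male, 1L, 0L)
  G[9, kids] <- ifelse(kid_male, 1L, 0L)
  G[9, kids[1]] <- 0L  # one male offspring lacks the allele
  pos <- c(100L, 200L, 300L, 400L, 500L, 1100L, 1200L, 1300L, 1400L)
  st <- site_table(rep("chr1", n), pos, rep("A", n), rep("G", n), G)
  contigs <- contig_map(c("tig1", "tig2"), "chr1", c(0, 1000), c(1000, 2000))
  res <- flag_coseg_and_contigs(st, sheet, contigs)
  expect_equal(sum(res$coseg), 8)
  expect_false(res$coseg[9])                    # mismatch, tolerance 0
  expect_equal(res$contigs, "tig1")             # 5 >= 4; tig2 has only 3
  res2 <- flag_coseg_and_contigs(st, sheet, contigs, mismatch_tolerance = 1)
  expect_true(res2$coseg[9])
  expect_equal(sort(res2$contigs), c("tig1", "tig2"))  # now 4 on tig2
  # mother carrying the allele disqualifies the site
  G2 <- G; G2[1, "mo"] <- 1L
  st2 <- site_table(rep("chr1", n), pos, rep("A", n), rep("G", n), G2)
  expect_equal(sum(flag_coseg_and_contigs(st2, sheet, contigs)$coseg), 7)
})
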