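mk_patterns <- function(p1, p2, p3, p4, pos = NULL, chrom = "chr1") {
  n <- length(p1)
  if (is.null(pos)) pos <- seq_len(n) * 100
  data.frame(chrom = chrom, pos = pos, p1 = p1, p2 = p2, p3 = p3, p4 = p4,
             abba = (1 - p1) * p2 * p3 * (1 - p4),
             baba = p1 * (1 - p2) * p3 * (1 - p4),
             stringsAsFactors = FALSE)
}

test_that("site patterns polarize by outgroup major allele", {
  ids <- c("a1", "a2", "b1", "b2", "c1", "c2", "o1", "o2")
  qt <- quartet_spec(ids[1:2], ids[3:4], ids[5:6], ids[7:8])
  G <- rbind(
    c(0, 0, 2, 2, 2, 2, 0, 0),   # (0,1,1,0) derived -> abba 1
    c(1, 0, 2, 1, 1, 2, 0, 0),   # frequencies (.25,.75,.75,0)
    c(2, 2, 0, 0, 0, 0, 2, 2),   # ALT ancestral: flips to (0,1,1,0)
    c(1, 1, 1, 1, 2, 0, 1, 1),   # outgroup 50/50 tie -> skipped
    c(0, 2, 2, 0, NA, NA, 0, 0)) # P3 uncalled -> skipped
  colnames(G) <- ids
  st <- site_table(rep("chr1", 5), (1:5) * 10L, rep("A", 5), rep("G", 5), G)
  p <- site_patterns(st, qt)
  expect_equal(nrow(p), 3)
  expect_equal(p$abba[1], 1)
  expect_equal(p$baba[1], 0)
  expect_equal(unlist(p[2, c("p1", "p2", "p3", "p4")], use.names = FALSE),
               c(0.25, 0.75, 0.75, 0))
  expect_equal(p$abba[3], 1)  # polarization flip
  expect_equal(attr(p, "n_skipped_tie"), 1)
  expect_equal(attr(p, "n_skipped_uncalled"), 1)
  expect_error(quartet_spec(ids[1:2], ids[2:3], ids[5:6], ids[7:8]),
               "disjoint")
})

test_that("pattern weights match the direct products", {
  p <- mk_patterns(0.2, 0.8, 0.5, 0)
  expect_equal(p$abba, 0.32)
  expect_equal(p$baba, 0.02)
  # p1 = p2 contributes zero to the numerator
  q <- mk_patterns(0.4, 0.4, 0.7, 0.1)
  expect_equal(q$abba, q$baba)
  set.seed(3)
  r <- mk_patterns(runif(20), runif(20), runif(20), runif(20) / 4)
  for (i in 1:20) {
    o <- oracle_patterns(r$p1[i], r$p2[i], r$p3[i], r$p4[i])
    expect_equal(r$abba[i], o$abba, tolerance = 1e-12)
    expect_equal(r$baba[i], o$baba, tolerance = 1e-12)
  }
})

test_that("Patterson's D hits its boundary and symmetry properties", {
  expect_equal(patterson_d(mk_patterns(rep(0, 5), rep(1, 5), rep(1, 5),
                                       rep(0, 5))), 1)
  set.seed(5)
  p <- mk_patterns(runif(50), runif(50), runif(50), runif(50) / 4)
  d <- patterson_d(p)
  swapped <- mk_patterns(p$p2, p$p1, p$p3, p$p4)
  expect_equal(patterson_d(swapped), -d, tolerance = 1e-12)
  expect_true(abs(d) <= 1)
  expect_warning(d0 <- patterson_d(mk_patterns(0.5, 0.5, 0, 0)), "denominator")
  expect_true(is.na(d0))
})

test_that("weighted block jackknife matches an independent computation", {
  set.seed(11)
  p <- mk_patterns(runif(240), runif(240), runif(240), runif(240) / 4)
  res <- jackknife_z(p, n_blocks = 12)
  # independent recomputation of the weighted delete-one variance
  blk <- ceiling(seq_len(240) / 20)
  num <- tapply(p$abba - p$baba, blk, sum)
  den <- tapply(p$abba + p$baba, blk, sum)
  D <- sum(num) / sum(den)
  g <- 12
  Dd <- vapply(1:g, function(j) sum(num[-j]) / sum(den[-j]), numeric(1))
  h <- sum(den) / den
  theta <- g * D - sum((1 - den / sum(den)) * Dd)
  tau <- h * D - (h - 1) * Dd
  se <- sqrt(mean((tau - theta)^2 / (h - 1)))
  expect_equal(res$D, D, tolerance = 1e-12)
  expect_equal(res$SE, se, tolerance = 1e-12)
  expect_equal(res$Z, D / se, tolerance = 1e-12)
  # equal-weight blocks reduce to the classic delete-one jackknife
  peq <- mk_patterns(rep(c(0.1, 0.3), 60), rep(c(0.8, 0.5), 60),
                     rep(0.6, 120), rep(0, 120))
  req <- jackknife_z(peq, n_blocks = 12)
  blk2 <- ceiling(seq_len(120) / 10)
  n2 <- tapply(peq$abba - peq$baba, blk2, sum)
  d2 <- tapply(peq$abba + peq$baba, blk2, sum)
  Dd2 <- vapply(1:12, function(j) sum(n2[-j]) / sum(d2[-j]), numeric(1))
  se_classic <- sqrt((12 - 1) / 12 * sum((Dd2 - mean(Dd2))^2))
  expect_equal(req$SE, se_classic, tolerance = 1e-12)
  # identical blocks: SE 0, Z flagged undefined
  pid <- mk_patterns(rep(0.2, 120), rep(0.6, 120), rep(0.5, 120), rep(0, 120))
  rid <- jackknife_z(pid, n_blocks = 12)
  expect_equal(rid$SE, 0)
  expect_true(is.na(rid$Z))
  expect_error(jackknife_z(p[1:5, ], n_blocks = 12), "10 usable")
})

test_that("fd_M reproduces its single-site anchors and window oracle", {
  w <- make_windows(c(chr1 = 1000), 1000, 1000)
  up <- fdm_track(mk_patterns(0, 0.5, 0.5, 0, pos = 500), w, min_sites = 1)
  expect_equal(up$value, 1)
  dn <- fdm_track(mk_patterns(0.5, 0, 0.5, 0, pos = 500), w, min_sites = 1)
  expect_equal(dn$value, -1)
  # no donor signal: p3 = 0 throughout -> numerator 0
  none <- fdm_track(mk_patterns(c(0.1, 0.3), c(0.4, 0.2), c(0, 0), c(0, 0),
                                pos = c(200, 700)), w, min_sites = 1)
  expect_true(is.na(none$value) || none$value == 0)
  # windows below min_sites are masked
  masked <- fdm_track(mk_patterns(0, 0.5, 0.5, 0, pos = 500), w, min_sites = 3)
  expect_true(is.na(masked$value))
  # random fixture equals the brute-force oracle; sign flips under P1<->P2
  set.seed(7)
  p <- mk_patterns(runif(30), runif(30), runif(30), runif(30) / 4,
                   pos = sort(sample(1000, 30)))
  tr <- fdm_track(p, w, min_sites = 1)
  expect_equal(tr$value, oracle_fdm(p$p1, p$p2, p$p3, p$p4), tolerance = 1e-12)
  ps <- mk_patterns(p$p2, p$p1, p$p3, p$p4, pos = p$pos)
  expect_equal(fdm_track(ps, w, min_sites = 1)$value, -tr$value,
               tolerance = 1e-12)
  expect_true(all(abs(tr$value) <= 1 + 1e-9, na.rm = TRUE))
})

test_that("pattern computation matches a genotype-count oracle on a fixture", {
  st <- random_site_table(50, 20, seed = 31, span = 1e5)
  ids <- st$samples
  qt <- quartet_spec(ids[1:6], ids[7:12], ids[13:17], ids[18:20])
  p <- site_patterns(st, qt)
  freq <- function(g) sum(g, na.rm = TRUE) / (2 * sum(!is.na(g)))
  kept <- 0
  for (i in seq_len(50)) {
    fo <- freq(st$geno[i, ids[18:20]])
    fs <- c(freq(st$geno[i, ids[1:6]]), freq(st$geno[i, ids[7:12]]),
            freq(st$geno[i, ids[13:17]]))
    if (any(is.nan(c(fs, fo))) || fo == 0.5) next
    kept <- kept + 1
    d <- if (fo > 0.5) 1 - c(fs, fo) else c(fs, fo)
    expect_equal(unlist(p[kept, c("p1", "p2", "p3", "p4")], use.names = FALSE),
                 d, tolerance = 1e-12)
    expect_equal(p$abba[kept], (1 - d[1]) * d[2] * d[3] * (1 - d[4]),
                 tolerance = 1e-12)
  }
  expect_equal(nrow(p), kept)
})

test_that("introgressed region calling merges overlapping outlier windows", {
  w <- make_windows(c(chr1 = 20000), 1000, 200)
  set.seed(13)
  pos <- sort(sample(20000, 400))
  p <- mk_patterns(runif(400, 0, 0.2), runif(400, 0, 0.2), rep(0.8, 400),
                   rep(0, 400), pos = pos)
  # plant a strong positive stretch at [5000, 8000)
  hot <- p$pos >= 5000 & p$pos < 8000
  p$p2[hot] <- 0.9; p$p1[hot] <- 0.05
  p$abba <- (1 - p$p1) * p$p2 * p$p3 * (1 - p$p4)
  p$baba <- p$p1 * (1 - p$p2) * p$p3 * (1 - p$p4)
  tr <- fdm_track(p, w)
  calls <- call_introgressed(tr)
  expect_gte(nrow(calls$regions), 1)
  top <- calls$regions[which.max(calls$regions$peak_fdm), ]
  expect_lt(top$start, 8000)
  expect_gt(top$end, 5000)
  # all-negative track yields an empty call set
  neg <- tr; neg$value <- -abs(neg$value)
  expect_equal(nrow(call_introgressed(neg)$regions), 0)
})
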