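## Tajima's D normalizing constants for n sampled chromosomes (vectorized)
tajima_constants <- function(n) {
  a1 <- vapply(n, function(k) {
    if (is.na(k) || k < 2) NA_real_ else sum(1 / seq_len(k - 1))
  }, numeric(1))
  a2 <- vapply(n, function(k) {
    if (is.na(k) || k < 2) NA_real_ else sum(1 / seq_len(k - 1)^2)
  }, numeric(1))
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed nucleotide diversity and Tajima's D
#'
#' Per window: `pi` = sum of per-site pairwise diversity over covered length
#' (monomorphic bases count in the denominator); `S` = segregating sites in
#' the sample subset; Watterson's `theta_w = S / a1`; and Tajima's D with the
#' standard normalizing constants. With missing data the window's sample size
#' `n` is the median per-site called-allele count; windows with `S = 0` or
#' `n < 3` have undefined D (`NA`).
#'
#' @param sites a [site_table()].
#' @param samples sample ids defining the population.
#' @param windows window table from [make_windows()].
#' @return `windows` plus `n_sites`, `S`, `pi_sum`, `pi`, `theta_w`, `n_eff`,
#'   `tajima_d`.
#' @export
window_diversity <- function(sites, samples, windows) {
  if (length(samples) == 0) stop("window_diversity: empty sample subset")
  G <- geno_of(sites, samples)
  cc <- allele_counts(G)
  segregating <- cc$alt > 0 & cc$alt < cc$n
  spi <- site_pi(cc$alt, cc$n)
  spi[is.na(spi)] <- 0
  per_site <- cbind(pi = spi, S = as.numeric(segregating))
  sums <- window_sums(sites$chrom, sites$pos - 1, per_site, windows)
  n_eff <- window_median_n(sites, cc$n, windows)
  S <- sums[, 2]
  const <- tajima_constants(ifelse(n_eff >= 2, n_eff, NA))
  theta_w <- S / const$a1
  num <- sums[, 1] - theta_w
  varD <- const$e1 * S + const$e2 * S * (S - 1)
  D <- ifelse(S > 0 & !is.na(n_eff) & n_eff >= 3 & varD > 0,
              num / sqrt(varD), NA_real_)
  windows$n_sites <- attr(sums, "n_sites")
  windows$S <- S
  windows$pi_sum <- sums[, 1]
  windows$pi <- sums[, 1] / windows$covered_length
  windows$theta_w <- theta_w
  windows$n_eff <- n_eff
  windows$tajima_d <- D
  windows
}

## internal: median per-site called-allele count per window
window_median_n <- function(sites, n_called, windows) {
  out <- rep(NA_real_, nrow(windows))
  for (chr in unique(windows$chrom)) {
    wi <- which(windows$chrom == chr)
    si <- which(sites$chrom == chr)
    if (!length(si)) next
    pos0 <- sites$pos[si] - 1
    rng <- window_site_range(pos0, windows$start[wi], windows$end[wi])
    nn <- n_called[si]
    out[wi] <- vapply(seq_along(wi), function(j) {
      if (rng$i2[j] < rng$i1[j]) return(NA_real_)
      stats::median(nn[rng$i1[j]:rng$i2[j]])
    }, numeric(1))
  }
  out
}

#' Windowed Weir-Cockerham Fst
#'
#' Computes the Weir & Cockerham (1984) variance components a (between
#' populations), b (between individuals within populations) and c (within
#' individuals) per site from the two groups' allele frequencies,
#' heterozygote frequencies and sample sizes, and reports the window ratio
#' `sum(a) / sum(a + b + c)`. Sites monomorphic across both groups contribute
#' nothing; sites where either group has no called genotype are skipped. The
#' estimator can be negative; a window with zero total variance is `NA`.
#'
#' @param sites a [site_table()].
#' @param group1,group2 sample id vectors (>= 2 diploid samples each).
#' @param windows window table from [make_windows()].
#' @return `windows` plus `sum_a`, `sum_abc`, `fst`.
#' @export
window_fst <- function(sites, group1, group2, windows) {
  if (length(group1) < 2 || length(group2) < 2) {
    stop("window_fst: both groups need >= 2 samples")
  }
  comp <- wc_site_components(geno_of(sites, group1), geno_of(sites, group2))
  sums <- window_sums(sites$chrom, sites$pos - 1,
                      cbind(comp$a, comp$a + comp$b + comp$c), windows)
  windows$sum_a <- sums[, 1]
  windows$sum_abc <- sums[, 2]
  windows$fst <- ifelse(sums[, 2] != 0, sums[, 1] / sums[, 2], NA_real_)
  windows
}

## internal: per-site WC84 components for two groups (r = 2).
## Returns NA components (treated as 0 in window sums) for unusable sites.
wc_site_components <- function(G1, G2) {
  n1 <- rowSums(!is.na(G1)); n2 <- rowSums(!is.na(G2))
  usable <- n1 >= 1 & n2 >= 1 & (n1 + n2) > 2  # nbar > 1 needed
  p1 <- rowSums(G1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(G2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(G1 == 1, na.rm = TRUE) / n1
  h2 <- rowSums(G2 == 1, na.rm = TRUE) / n2
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  c <- hbar / 2
  a[!usable] <- NA; b[!usable] <- NA; c[!usable] <- NA
  list(a = a, b = b, c = c)
}
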