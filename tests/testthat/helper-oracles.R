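# Independent brute-force oracles and fixture builders. These deliberately
# re-derive every statistic from first principles by enumeration, sharing no
# code with the package implementations they check.

# per-site pi by literal enumeration of haplotype pairs
oracle_site_pi <- function(alt, n) {
  hap <- c(rep(1, alt), rep(0, n - alt))
  if (n < 2) return(NA_real_)
  diffs <- 0; pairs <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pairs <- pairs + 1
    if (hap[i] != hap[j]) diffs <- diffs + 1
  }
  diffs / pairs
}

# windowed diversity + Tajima's D, textbook form, no missing-data shortcuts
oracle_diversity <- function(G, covered_length) {
  n_called <- apply(G, 1, function(g) 2 * sum(!is.na(g)))
  alt <- apply(G, 1, function(g) sum(g, na.rm = TRUE))
  pi_sum <- 0
  for (i in seq_len(nrow(G))) {
    if (n_called[i] >= 2) {
      p <- oracle_site_pi(alt[i], n_called[i])
      pi_sum <- pi_sum + p
    }
  }
  S <- sum(alt > 0 & alt < n_called)
  n <- stats::median(n_called)
  if (S == 0 || n < 3) {
    return(list(pi_sum = pi_sum, S = S, tajima_d = NA_real_))
  }
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  D <- (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(pi_sum = pi_sum, S = S, tajima_d = D)
}

# Weir & Cockerham 1984 variance components, written out per site
oracle_wc_fst <- function(G1, G2) {
  sum_a <- 0; sum_abc <- 0
  for (i in seq_len(nrow(G1))) {
    g1 <- G1[i, ][!is.na(G1[i, ])]
    g2 <- G2[i, ][!is.na(G2[i, ])]
    n1 <- length(g1); n2 <- length(g2)
    if (n1 < 1 || n2 < 1 || n1 + n2 <= 2) next
    r <- 2
    p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
    h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
    nbar <- mean(c(n1, n2))
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                          (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                  hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    sum_a <- sum_a + a
    sum_abc <- sum_abc + a + b + cc
  }
  if (sum_abc == 0) NA_real_ else sum_a / sum_abc
}

# folded SFS tally for full-call fixtures
oracle_folded_sfs <- function(G) {
  n <- 2 * ncol(G)
  counts <- integer(floor(n / 2))
  for (i in seq_len(nrow(G))) {
    c1 <- sum(G[i, ])
    k <- min(c1, n - c1)
    if (k >= 1) counts[k] <- counts[k] + 1
  }
  counts
}

# per-site ABBA/BABA weights and fd_M pieces straight from the definitions
oracle_patterns <- function(p1, p2, p3, p4) {
  list(abba = (1 - p1) * p2 * p3 * (1 - p4),
       baba = p1 * (1 - p2) * p3 * (1 - p4))
}

oracle_fdm <- function(p1, p2, p3, p4) {
  num <- den <- numeric(length(p1))
  for (i in seq_along(p1)) {
    w <- oracle_patterns(p1[i], p2[i], p3[i], p4[i])
    num[i] <- w$abba - w$baba
    if (p2[i] >= p1[i]) {
      pD <- max(p2[i], p3[i])
      wD <- oracle_patterns(p1[i], pD, pD, p4[i])
      den[i] <- wD$abba - wD$baba
    } else {
      pD <- max(p1[i], p3[i])
      wD <- oracle_patterns(pD, p2[i], pD, p4[i])
      den[i] <- -(wD$abba - wD$baba)
    }
  }
  sum(num) / sum(den)
}

# slow NG86: recursive pathway enumeration, independent of the package's
# table-driven implementation
oracle_ng86 <- function(s1, s2) {
  code <- Biostrings::GENETIC_CODE
  aa <- function(cd) unname(code[cd])
  is_stop <- function(cd) aa(cd) == "*"
  bases <- c("A", "C", "G", "T")
  codons1 <- substring(s1, seq(1, nchar(s1), 3), seq(3, nchar(s1), 3))
  codons2 <- substring(s2, seq(1, nchar(s2), 3), seq(3, nchar(s2), 3))
  syn_sites <- function(cd) {
    s <- 0
    for (i in 1:3) for (b in bases) {
      if (substr(cd, i, i) == b) next
      nb <- cd; substr(nb, i, i) <- b
      if (!is_stop(nb) && aa(nb) == aa(cd)) s <- s + 1 / 3
    }
    s
  }
  paths <- function(c1, c2) {
    dpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(dpos)) return(list())
    res <- list()
    recurse <- function(cur, remaining, sd, nd, crossed_stop) {
      if (!length(remaining)) {
        res[[length(res) + 1]] <<- list(sd = sd, nd = nd, stop = crossed_stop)
        return()
      }
      for (p in remaining) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        syn <- !is_stop(cur) && !is_stop(nxt) && aa(nxt) == aa(cur)
        recurse(nxt, setdiff(remaining, p),
                sd + as.numeric(syn), nd + as.numeric(!syn),
                crossed_stop || is_stop(nxt))
      }
    }
    recurse(c1, dpos, 0, 0, FALSE)
    res
  }
  S <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(codons1)) {
    S <- S + (syn_sites(codons1[i]) + syn_sites(codons2[i])) / 2
    ps <- paths(codons1[i], codons2[i])
    if (!length(ps)) next
    ok <- Filter(function(p) !p$stop, ps)
    if (!length(ok)) ok <- ps
    Sd <- Sd + mean(vapply(ok, `[[`, 0, "sd"))
    Nd <- Nd + mean(vapply(ok, `[[`, 0, "nd"))
  }
  N <- 3 * length(codons1) - S
  ps <- Sd / S; pn <- Nd / N
  list(Ka = -3 / 4 * log(1 - 4 / 3 * pn), Ks = -3 / 4 * log(1 - 4 / 3 * ps))
}

# random genotype fixture
random_site_table <- function(n_sites = 50, n_samples = 10, seed = 1,
                              miss_rate = 0.05, chrom = "chr1",
                              span = 1e5) {
  set.seed(seed)
  pos <- sort(sample.int(span, n_sites))
  p <- stats::rbeta(n_sites, 0.5, 0.5)
  G <- matrix(stats::rbinom(n_sites * n_samples, 2, p), nrow = n_sites)
  G[matrix(stats::runif(length(G)) < miss_rate, nrow = n_sites)] <- NA
  colnames(G) <- sprintf("s%02d", seq_len(n_samples))
  site_table(rep(chrom, n_sites), pos, rep("A", n_sites), rep("G", n_sites), G)
}

# two-sex sample sheet for a fixture
fixture_sheet <- function(samples, n_male = floor(length(samples) / 2)) {
  sample_sheet(samples, group = "pop",
               sex = c(rep("M", n_male), rep("F", length(samples) - n_male)))
}
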