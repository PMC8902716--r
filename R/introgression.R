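#' Four-taxon quartet specification
#'
#' Maps the fixed topology `[[[P1, P2], P3], O]` onto sample subsets: `P1`
#' and `P2` are the sister ingroups tested for asymmetric allele sharing
#' with the candidate donor `P3`, polarized by the outgroup `O`.
#'
#' @param P1,P2,P3,O character vectors of sample ids (disjoint, each >= 1).
#' @return A list of class `quartet_spec`.
#' @export
quartet_spec <- function(P1, P2, P3, O) {
  g <- list(P1 = P1, P2 = P2, P3 = P3, O = O)
  if (any(lengths(g) < 1)) stop("quartet_spec: every group needs >= 1 sample")
  all_ids <- unlist(g)
  if (anyDuplicated(all_ids)) stop("quartet_spec: groups must be disjoint")
  class(g) <- "quartet_spec"
  g
}

#' Per-site ABBA/BABA patterns
#'
#' Polarizes each site by the outgroup major allele (50/50 outgroup ties are
#' skipped and counted), computes derived allele frequencies `p1..p4` per
#' group, and the frequency-weighted pattern weights
#' `abba = (1-p1) p2 p3 (1-p4)` and `baba = p1 (1-p2) p3 (1-p4)`. Sites where
#' any group is entirely uncalled are skipped.
#'
#' @param sites a [site_table()].
#' @param quartet a [quartet_spec()].
#' @return A data frame `chrom`, `pos`, `p1..p4`, `abba`, `baba`, with
#'   attributes `n_skipped_tie`, `n_skipped_uncalled`.
#' @export
site_patterns <- function(sites, quartet) {
  freq <- lapply(quartet, function(ids) {
    cc <- allele_counts(geno_of(sites, ids))
    list(f = ifelse(cc$n > 0, cc$alt / cc$n, NA_real_), n = cc$n)
  })
  called <- freq$P1$n > 0 & freq$P2$n > 0 & freq$P3$n > 0 & freq$O$n > 0
  tie <- called & freq$O$f == 0.5
  use <- called & !tie
  # ancestral = outgroup major allele; derived frequency flips when ALT is
  # ancestral
  flip <- freq$O$f > 0.5
  d <- function(f) ifelse(flip, 1 - f, f)
  p1 <- d(freq$P1$f)[use]; p2 <- d(freq$P2$f)[use]
  p3 <- d(freq$P3$f)[use]; p4 <- d(freq$O$f)[use]
  out <- data.frame(chrom = sites$chrom[use], pos = sites$pos[use],
                    p1 = p1, p2 = p2, p3 = p3, p4 = p4,
                    abba = (1 - p1) * p2 * p3 * (1 - p4),
                    baba = p1 * (1 - p2) * p3 * (1 - p4),
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped_tie") <- sum(tie)
  attr(out, "n_skipped_uncalled") <- sum(!called)
  out
}

#' Patterson's D
#'
#' `D = sum(abba - baba) / sum(abba + baba)` over site patterns. Positive D
#' indicates excess allele sharing between P2 and P3, negative between P1
#' and P3.
#'
#' @param patterns output of [site_patterns()].
#' @return D, or `NA` (with a warning) when the denominator is zero.
#' @export
patterson_d <- function(patterns) {
  den <- sum(patterns$abba + patterns$baba)
  if (den == 0) {
    warning("patterson_d: zero denominator (no informative sites)")
    return(NA_real_)
  }
  sum(patterns$abba - patterns$baba) / den
}

#' Weighted block-jackknife Z score for Patterson's D
#'
#' Splits sites into `n_blocks` contiguous equal-site blocks, computes
#' delete-one-block estimates, and the weighted jackknife variance of Busing
#' et al. (1999) with block weights proportional to their informative
#' (`abba + baba`) weight sums. `Z = D / SE`.
#'
#' @param patterns output of [site_patterns()].
#' @param n_blocks number of contiguous blocks (default 100; at least 10
#'   non-empty blocks are required).
#' @return A list `D`, `SE`, `Z`, `n_blocks`, `n_sites`.
#' @export
jackknife_z <- function(patterns, n_blocks = 100) {
  ns <- nrow(patterns)
  blk <- ceiling(seq_len(ns) / ns * n_blocks)
  num <- tapply(patterns$abba - patterns$baba, blk, sum)
  den <- tapply(patterns$abba + patterns$baba, blk, sum)
  keep <- !is.na(den) & den > 0
  num <- num[keep]; den <- den[keep]
  g <- length(num)
  if (g < 10) stop("jackknife_z: fewer than 10 usable blocks")
  tot_num <- sum(num); tot_den <- sum(den)
  if (tot_den == 0) stop("jackknife_z: zero total denominator")
  D <- tot_num / tot_den
  D_del <- (tot_num - num) / (tot_den - den)
  h <- tot_den / den  # inverse block weights
  # Busing, Meijer & van der Leeden (1999) weighted delete-one jackknife
  theta_J <- g * D - sum((1 - den / tot_den) * D_del)
  tau <- h * D - (h - 1) * D_del
  var_J <- sum((tau - theta_J)^2 / (h - 1)) / g
  SE <- sqrt(var_J)
  list(D = D, SE = SE,
       Z = if (SE > 0) D / SE else NA_real_,
       n_blocks = g, n_sites = ns)
}

#' Windowed fd_M admixture-fraction track
#'
#' Malinsky's modified f(d) statistic per window: the ABBA-BABA imbalance
#' normalized by its value under complete sharing with a dynamic donor. Per
#' site, when `p2 >= p1` the donor frequency `pD = max(p2, p3)` replaces
#' both P2 and P3 in the pattern weights; when `p1 > p2`, `pD = max(p1, p3)`
#' replaces both P1 and P3 and the contribution is negated, making fd_M
#' positive for P2-P3 sharing and negative for P1-P3 sharing, bounded by
#' construction in \[-1, 1\].
#'
#' @param patterns output of [site_patterns()].
#' @param windows window table from [make_windows()] (1-kb windows with
#'   200-bp steps in the default scan).
#' @param min_sites minimum informative sites per window (default 3); below
#'   it the window is masked (`NA`).
#' @return `windows` plus `n_sites`, `numerator`, `denominator`, `value`
#'   (fd_M).
#' @export
fdm_track <- function(patterns, windows, min_sites = 3) {
  p1 <- patterns$p1; p2 <- patterns$p2; p3 <- patterns$p3; p4 <- patterns$p4
  num <- patterns$abba - patterns$baba
  pD2 <- pmax(p2, p3)
  den2 <- (1 - p1) * pD2 * pD2 * (1 - p4) - p1 * (1 - pD2) * pD2 * (1 - p4)
  pD1 <- pmax(p1, p3)
  den1 <- -((1 - pD1) * p2 * pD1 * (1 - p4) - pD1 * (1 - p2) * pD1 * (1 - p4))
  den <- ifelse(p2 >= p1, den2, den1)
  sums <- window_sums(patterns$chrom, patterns$pos - 1, cbind(num, den),
                      windows)
  n_in <- attr(sums, "n_sites")
  value <- ifelse(n_in >= min_sites & sums[, 2] != 0,
                  sums[, 1] / sums[, 2], NA_real_)
  stopifnot(all(is.na(value) | (value >= -1 - 1e-9 & value <= 1 + 1e-9)))
  windows$n_sites <- n_in
  windows$numerator <- sums[, 1]
  windows$denominator <- sums[, 2]
  windows$value <- value
  windows
}

#' Call candidate introgressed regions from an fd_M track
#'
#' The cutoff is the 95th nearest-rank percentile of the positive finite
#' fd_M values; windows at or above it are merged where they overlap or
#' touch (gap 0) into candidate introgression regions. (Formal
#' introgression-vs-ILS testing is out of scope; calls are candidates.)
#'
#' @param track output of [fdm_track()].
#' @param q upper-tail fraction among positive values (default 0.05).
#' @return A list with `cutoff` and `regions` (data frame `chrom`, `start`,
#'   `end`, `peak_fdm`).
#' @export
call_introgressed <- function(track, q = 0.05) {
  pos_vals <- track$value[!is.na(track$value) & track$value > 0]
  if (!length(pos_vals)) {
    return(list(cutoff = NA_real_,
                regions = data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), peak_fdm = numeric())))
  }
  cutoff <- threshold_by_quantile(pos_vals, q)
  pass <- !is.na(track$value) & track$value >= cutoff & track$value > 0
  if (!any(pass)) {
    return(list(cutoff = cutoff,
                regions = data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), peak_fdm = numeric())))
  }
  merged <- merge_intervals(interval_set(track$chrom[pass], track$start[pass],
                                         track$end[pass]), max_gap = 0)
  peak <- vapply(seq_len(nrow(merged)), function(i) {
    sel <- pass & track$chrom == merged$chrom[i] &
      track$start < merged$end[i] & track$end > merged$start[i]
    max(track$value[sel])
  }, numeric(1))
  regions <- as.data.frame(merged)
  regions$peak_fdm <- peak
  list(cutoff = cutoff, regions = regions)
}

#' Genome-wide introgression scan
#'
#' Convenience wrapper: site patterns, Patterson's D with jackknife Z, the
#' fd_M track, and candidate region calls for one quartet.
#'
#' @param sites a [site_table()].
#' @param quartet a [quartet_spec()].
#' @param chrom_lengths named lengths for the window grid.
#' @param cfg a [dioscan_config()].
#' @return A list `d` (jackknife result), `track`, `calls`.
#' @export
introgression_scan <- function(sites, quartet, chrom_lengths,
                               cfg = dioscan_config()) {
  patterns <- site_patterns(sites, quartet)
  d <- jackknife_z(patterns, n_blocks = cfg$jackknife_blocks)
  windows <- make_windows(chrom_lengths, cfg$fdm_window, cfg$fdm_step)
  track <- fdm_track(patterns, windows, min_sites = cfg$fdm_min_sites)
  calls <- call_introgressed(track, q = cfg$fdm_q)
  list(d = d, track = track, calls = calls)
}
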