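#' Wild/cultivated diversity-ratio track
#'
#' Per window, the ratio of wild to cultivated nucleotide diversity
#' (`pi_wild / pi_cultivated`); elevated values mark diversity lost to
#' domestication. Windows where the cultivated group has zero diversity are
#' assigned `+Inf` when the wild group is still variable (complete local
#' fixation — the strongest signal — must rank above every finite value) and
#' masked (`NA`) when both are invariant.
#'
#' @param sites a [site_table()].
#' @param wild,cultivated sample id vectors (>= 2 each).
#' @param windows window table (100-kb windows, 20-kb steps in the default
#'   scan).
#' @return `windows` plus `pi_wild`, `pi_cultivated`, `value`.
#' @export
pi_ratio_track <- function(sites, wild, cultivated, windows) {
  if (length(wild) < 2 || length(cultivated) < 2) {
    stop("pi_ratio_track: both groups need >= 2 samples")
  }
  dw <- window_diversity(sites, wild, windows)
  dc <- window_diversity(sites, cultivated, windows)
  value <- ifelse(dc$pi > 0, dw$pi / dc$pi,
                  ifelse(dw$pi > 0, Inf, NA_real_))
  windows$pi_wild <- dw$pi
  windows$pi_cultivated <- dc$pi
  windows$value <- value
  windows
}

#' Folded-SFS generalized likelihood ratio track
#'
#' A sweep statistic capturing local distortion of the folded site-frequency
#' spectrum: per grid window with `m` polymorphic sites and folded class
#' counts `m_k`, `GLR = 2 * sum_k m_k * log(phat_k / q_k)` with `phat_k =
#' m_k / m` and `q_k` the genome-wide class proportions. Non-negative by
#' construction (a scaled Kullback-Leibler divergence); windows with fewer
#' than `min_sites` polymorphic sites are masked. To keep the null
#' distribution stable on windows holding tens of SNPs, the folded classes
#' are first grouped into at most `n_bins` contiguous bins of roughly equal
#' genome-wide mass; a sweep concentrates mass in the rarest bin. This is a
#' deliberately simple SFS-deviation statistic, not a sweep-model composite
#' likelihood with spatial decay.
#'
#' @param sites a [site_table()].
#' @param cultivated sample ids of the scanned (cultivated) population.
#' @param windows grid windows (20-kb tiling in the default scan).
#' @param min_sites minimum polymorphic sites per window (default 10).
#' @param n_bins maximum frequency bins (default 5).
#' @return `windows` plus `m` (polymorphic sites) and `value` (GLR).
#' @export
sfs_glr_track <- function(sites, cultivated, windows, min_sites = 10,
                          n_bins = 5) {
  G <- geno_of(sites, cultivated)
  cc <- allele_counts(G)
  n_max <- max(cc$n)
  k <- folded_class(cc$alt, cc$n, n_max)
  kmax <- floor(n_max / 2)
  bg_class <- tabulate(k[!is.na(k)], nbins = kmax)
  if (sum(bg_class > 0) < 2) {
    warning("sfs_glr_track: degenerate background SFS; track masked")
    windows$m <- 0L
    windows$value <- NA_real_
    return(windows)
  }
  # contiguous equal-mass binning of the folded classes
  cum_prev <- (cumsum(bg_class) - bg_class) / sum(bg_class)
  bin_of <- cummax(pmin(floor(cum_prev * n_bins) + 1, n_bins))
  kmax_b <- max(bin_of)
  bg <- as.vector(tapply(bg_class, factor(bin_of, levels = seq_len(kmax_b)), sum))
  bg[is.na(bg)] <- 0
  q <- bg / sum(bg)
  poly <- !is.na(k)
  kb <- bin_of[k]
  ind <- matrix(0, nrow = n_sites(sites), ncol = kmax_b)
  ind[cbind(which(poly), kb[poly])] <- 1
  mk <- window_sums(sites$chrom, sites$pos - 1, ind, windows)
  m <- rowSums(mk)
  glr <- vapply(seq_len(nrow(windows)), function(i) {
    if (m[i] < min_sites) return(NA_real_)
    mi <- mk[i, ]
    nz <- mi > 0
    2 * sum(mi[nz] * log((mi[nz] / m[i]) / q[nz]))
  }, numeric(1))
  windows$m <- m
  windows$value <- glr
  windows
}

#' Call candidate selective-sweep regions
#'
#' Takes the top-`q` outlier windows of each supplied track (quantile rule
#' of [threshold_by_quantile()]; `+Inf` ranks top), extends them by `flank`
#' bp, merges across tracks with gap at most `merge_gap` bp, and annotates
#' each resulting region with its supporting statistics, peak values, and
#' overlapping genes. Regions supported by both statistics are flagged
#' high-confidence.
#'
#' @param tracks named list of tracks (data frames with `chrom`, `start`,
#'   `end`, `value`), e.g. `list(pi_ratio = ..., glr = ...)`.
#' @param q per-track upper-tail fraction (default 0.01).
#' @param flank flank in bp added to outlier windows (default 2000).
#' @param merge_gap merge gap in bp (default 4000, inclusive).
#' @param genes optional gene intervals (`chrom`, `start`, `end`, `name`).
#' @return A list with per-track `cutoffs` and `regions`: `chrom`, `start`,
#'   `end`, `support` (comma-joined track names), `high_confidence`,
#'   per-track peak values, `genes`.
#' @export
call_sweeps <- function(tracks, q = 0.01, flank = 2000, merge_gap = 4000,
                        genes = NULL) {
  stopifnot(length(tracks) >= 1, !is.null(names(tracks)))
  cutoffs <- list()
  outliers <- list()
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    vals <- tr$value[!is.na(tr$value)]
    if (!length(vals)) { cutoffs[[nm]] <- NA_real_; next }
    cutoffs[[nm]] <- threshold_by_quantile(vals, q)
    pass <- !is.na(tr$value) & tr$value >= cutoffs[[nm]]
    if (any(pass)) {
      outliers[[nm]] <- data.frame(chrom = tr$chrom[pass],
                                   start = pmax(tr$start[pass] - flank, 0),
                                   end = tr$end[pass] + flank,
                                   track = nm, stringsAsFactors = FALSE)
    }
  }
  if (!length(outliers)) {
    return(list(cutoffs = cutoffs,
                regions = data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), support = character(),
                                     high_confidence = logical())))
  }
  all_out <- do.call(rbind, outliers)
  merged <- merge_intervals(interval_set(all_out$chrom, all_out$start,
                                         all_out$end), max_gap = merge_gap)
  regions <- as.data.frame(merged)
  regions$support <- ""
  regions$high_confidence <- FALSE
  for (nm in names(tracks)) {
    regions[[paste0("peak_", nm)]] <- NA_real_
  }
  for (i in seq_len(nrow(regions))) {
    sup <- character(0)
    for (nm in names(outliers)) {
      o <- outliers[[nm]]
      hit <- o$chrom == regions$chrom[i] & o$start < regions$end[i] &
        o$end > regions$start[i]
      if (any(hit)) {
        sup <- c(sup, nm)
        tr <- tracks[[nm]]
        sel <- tr$chrom == regions$chrom[i] &
          tr$start < regions$end[i] & tr$end > regions$start[i] &
          !is.na(tr$value)
        if (any(sel)) regions[[paste0("peak_", nm)]][i] <- max(tr$value[sel])
      }
    }
    regions$support[i] <- paste(sup, collapse = ",")
    regions$high_confidence[i] <- length(sup) >= 2
  }
  if (!is.null(genes)) {
    regions$genes <- vapply(seq_len(nrow(regions)), function(i) {
      hit <- genes$chrom == regions$chrom[i] &
        genes$start < regions$end[i] & genes$end > regions$start[i]
      paste(genes$name[hit], collapse = ",")
    }, character(1))
  }
  list(cutoffs = cutoffs, regions = regions)
}

#' Domestication-sweep scan
#'
#' Convenience wrapper: builds the diversity-ratio and SFS-GLR tracks on the
#' configured window grids and calls candidate sweep regions.
#'
#' @param sites a [site_table()].
#' @param wild,cultivated sample id vectors.
#' @param chrom_lengths named chromosome lengths.
#' @param cfg a [dioscan_config()].
#' @param genes optional gene intervals.
#' @return A list `pi_ratio`, `glr` (tracks) and `calls`.
#' @export
sweep_scan <- function(sites, wild, cultivated, chrom_lengths,
                       cfg = dioscan_config(), genes = NULL) {
  w_pi <- make_windows(chrom_lengths, cfg$sweep_window, cfg$sweep_step)
  w_glr <- make_windows(chrom_lengths, cfg$glr_grid, cfg$glr_grid)
  pi_tr <- pi_ratio_track(sites, wild, cultivated, w_pi)
  glr_tr <- sfs_glr_track(sites, cultivated, w_glr,
                          min_sites = cfg$glr_min_sites)
  calls <- call_sweeps(list(pi_ratio = pi_tr, glr = glr_tr), q = cfg$sweep_q,
                       flank = cfg$sweep_flank, merge_gap = cfg$sweep_merge_gap,
                       genes = genes)
  list(pi_ratio = pi_tr, glr = glr_tr, calls = calls)
}
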