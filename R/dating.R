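## ---- NG86 codon machinery ---------------------------------------------
## Lazily built lookup tables for the standard genetic code: per-codon
## synonymous site fractions (changes to stop codons count as nonsynonymous)
## and pathway-averaged synonymous/nonsynonymous difference counts per codon
## pair, with stop-crossing pathways excluded.
.ng86 <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(.ng86$syn_sites)) return(.ng86)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  bases <- c("A", "C", "G", "T")
  aa <- unname(code)
  names(aa) <- codons
  is_stop <- aa == "*"

  syn <- stats::setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    if (is_stop[cd]) { syn[cd] <- NA; next }
    s <- 0
    cs <- strsplit(cd, "")[[1]]
    for (i in 1:3) {
      for (b in setdiff(bases, cs[i])) {
        nb <- cs; nb[i] <- b
        nb <- paste(nb, collapse = "")
        if (!is_stop[nb] && aa[nb] == aa[cd]) s <- s + 1 / 3
      }
    }
    syn[cd] <- s
  }
  .ng86$codons <- codons
  .ng86$aa <- aa
  .ng86$is_stop <- is_stop
  .ng86$syn_sites <- syn
  .ng86$pair_cache <- new.env(parent = emptyenv())
  .ng86
}

## pathway-averaged (sd, nd) between two codons; equal weight over orders of
## the differing positions, pathways with stop intermediates dropped (all
## pathways used if every one crosses a stop)
ng86_pair_diff <- function(c1, c2) {
  tb <- ng86_tables()
  if (c1 == c2) return(c(0, 0))
  key <- paste0(c1, c2)
  hit <- tb$pair_cache[[key]]
  if (!is.null(hit)) return(hit)
  s1 <- strsplit(c1, "")[[1]]; s2 <- strsplit(c2, "")[[1]]
  dpos <- which(s1 != s2)
  perms <- switch(length(dpos),
                  list(dpos),
                  list(dpos, rev(dpos)),
                  {
                    p <- list()
                    for (i in 1:3) for (j in 1:3) for (k in 1:3) {
                      if (length(unique(c(i, j, k))) == 3) {
                        p[[length(p) + 1]] <- dpos[c(i, j, k)]
                      }
                    }
                    p
                  })
  step_sn <- function(ca, cb) {
    if (tb$aa[ca] == tb$aa[cb]) c(1, 0) else c(0, 1)
  }
  valid <- list()
  all_paths <- list()
  for (ord in perms) {
    cur <- s1
    sd <- 0; nd <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur; nxt[p] <- s2[p]
      ca <- paste(cur, collapse = ""); cb <- paste(nxt, collapse = "")
      if (tb$is_stop[cb] && cb != c2) ok <- FALSE
      if (tb$is_stop[ca] || tb$is_stop[cb]) {
        nd <- nd + 1  # counted only on the all-paths fallback
      } else {
        sn <- step_sn(ca, cb); sd <- sd + sn[1]; nd <- nd + sn[2]
      }
      cur <- nxt
    }
    all_paths[[length(all_paths) + 1]] <- c(sd, nd)
    if (ok) valid[[length(valid) + 1]] <- c(sd, nd)
  }
  use <- if (length(valid)) valid else all_paths
  out <- Reduce(`+`, use) / length(use)
  assign(key, out, envir = tb$pair_cache)
  out
}

split_codons <- function(seq) {
  seq <- toupper(gsub("\\s", "", seq))
  if (nchar(seq) %% 3 != 0) stop("sequence length not divisible by 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' Nei-Gojobori (1986) Ka and Ks
#'
#' Counts synonymous and nonsynonymous sites per codon (fraction of one-step
#' changes that preserve the amino acid; changes to stop codons count as
#' nonsynonymous), averaged over the two sequences, and pathway-averaged
#' synonymous/nonsynonymous differences for each codon pair (all orders of
#' the differing positions weighted equally; pathways crossing a stop codon
#' are excluded). Proportions `ps = Sd/S` and `pn = Nd/N` are Jukes-Cantor
#' corrected: `Ks = -(3/4) log(1 - (4/3) ps)`, likewise Ka.
#'
#' @param seq1,seq2 codon-aligned DNA strings of equal length, multiple of
#'   3, no internal stop codons. Codons containing gaps (`-`) or `N` in
#'   either sequence are skipped.
#' @return A list with `Ka`, `Ks`, `ka_ks` (NA when `Ks` is 0), and the raw
#'   counts `S`, `N`, `Sd`, `Nd`.
#' @export
ng86_kaks <- function(seq1, seq2) {
  tb <- ng86_tables()
  c1 <- split_codons(seq1); c2 <- split_codons(seq2)
  if (length(c1) != length(c2)) stop("ng86_kaks: sequences differ in length")
  ok <- !grepl("[^ACGT]", c1) & !grepl("[^ACGT]", c2)
  c1 <- c1[ok]; c2 <- c2[ok]
  if (!length(c1)) stop("ng86_kaks: no ungapped codons")
  if (any(tb$is_stop[c1]) || any(tb$is_stop[c2])) {
    stop("ng86_kaks: internal stop codon")
  }
  S <- (sum(tb$syn_sites[c1]) + sum(tb$syn_sites[c2])) / 2
  N <- 3 * length(c1) - S
  sd <- 0; nd <- 0
  for (i in seq_along(c1)) {
    d <- ng86_pair_diff(c1[i], c2[i])
    sd <- sd + d[1]; nd <- nd + d[2]
  }
  ps <- sd / S; pn <- nd / N
  if (ps >= 3 / 4 || pn >= 3 / 4) {
    stop("ng86_kaks: substitution saturation (proportion >= 3/4)")
  }
  Ks <- -3 / 4 * log(1 - 4 / 3 * ps)
  Ka <- -3 / 4 * log(1 - 4 / 3 * pn)
  list(Ka = Ka, Ks = Ks,
       ka_ks = if (Ks > 0) Ka / Ks else NA_real_,
       S = S, N = N, Sd = sd, Nd = nd)
}

#' Kimura two-parameter distance
#'
#' `K = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` from the transition
#' proportion `P` and transversion proportion `Q` of an ungapped pairwise
#' alignment. Columns with gaps or ambiguous bases are dropped.
#'
#' @param seq1,seq2 aligned DNA strings of equal length.
#' @return A list with `K`, `P`, `Q`, `n_sites`.
#' @export
k2p_distance <- function(seq1, seq2) {
  a <- strsplit(toupper(seq1), "")[[1]]
  b <- strsplit(toupper(seq2), "")[[1]]
  if (length(a) != length(b)) stop("k2p_distance: sequences differ in length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0) stop("k2p_distance: no comparable sites")
  diff <- a != b
  transition <- diff & ((a %in% c("A", "G")) == (b %in% c("A", "G")))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
    stop("k2p_distance: substitution saturation")
  }
  list(K = -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q),
       P = P, Q = Q, n_sites = n)
}

#' Divergence time from a substitution distance
#'
#' `T = K / (2 r)` years, for a pairwise distance `K` (synonymous `Ks` for
#' X/Y gene pairs, K2P `K` for the two LTRs of a retroelement) and a
#' substitution rate `r` per site per year (default 2.8e-9, an
#' Amaranthaceae molecular-clock calibration).
#'
#' @param K non-negative substitution distance.
#' @param r substitution rate per site per year.
#' @return Age in years.
#' @examples
#' divergence_time(0.0056)  # 1e6 years
#' @export
divergence_time <- function(K, r = 2.8e-9) {
  if (any(r <= 0)) stop("divergence_time: r must be positive")
  if (any(K < 0)) stop("divergence_time: negative distance")
  K / (2 * r)
}

#' Date aligned sequence pairs
#'
#' Applies [ng86_kaks()] (`mode = "gene"`) or [k2p_distance()]
#' (`mode = "ltr"`) to each pair and converts the synonymous (or total)
#' distance to an age via [divergence_time()].
#'
#' @param pairs a named list of `list(seq1, seq2)` character pairs, or the
#'   result of [read_pair_fasta()].
#' @param mode `"gene"` (NG86, `T = Ks/2r`) or `"ltr"` (K2P, `T = K/2r`).
#' @param r substitution rate per site per year.
#' @return A data frame with one row per pair: `pair_id`, `Ka`, `Ks`,
#'   `ka_ks`, `K`, `T_years`; pairs hitting saturation get `NA` and a
#'   warning.
#' @export
date_pairs <- function(pairs, mode = c("gene", "ltr"), r = 2.8e-9) {
  mode <- match.arg(mode)
  rows <- lapply(names(pairs), function(id) {
    p <- pairs[[id]]
    res <- tryCatch({
      if (mode == "gene") {
        est <- ng86_kaks(p[[1]], p[[2]])
        data.frame(pair_id = id, Ka = est$Ka, Ks = est$Ks, ka_ks = est$ka_ks,
                   K = NA_real_, T_years = divergence_time(est$Ks, r))
      } else {
        est <- k2p_distance(p[[1]], p[[2]])
        data.frame(pair_id = id, Ka = NA_real_, Ks = NA_real_,
                   ka_ks = NA_real_, K = est$K,
                   T_years = divergence_time(est$K, r))
      }
    }, error = function(e) {
      warning("pair ", id, ": ", conditionMessage(e), call. = FALSE)
      data.frame(pair_id = id, Ka = NA_real_, Ks = NA_real_, ka_ks = NA_real_,
                 K = NA_real_, T_years = NA_real_)
    })
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "rate") <- r
  attr(out, "method") <- if (mode == "gene") "NG86" else "K2P"
  out
}

#' Summarize divergence per stratum
#'
#' Per-stratum sample size, mean and median age and Ka/Ks, plus two-sample
#' permutation p-values (difference of mean `T_years`) between every pair of
#' strata with at least two members each. Permutation tests are used in
#' place of t-tests to avoid normality assumptions on small stratum sizes.
#'
#' @param dated output of [date_pairs()].
#' @param assignment data frame with `pair_id` and `stratum`.
#' @param n_permutations permutations per comparison.
#' @return A list with `summary` (per-stratum table) and `comparisons`
#'   (pairwise permutation p-values).
#' @export
stratum_summary <- function(dated, assignment, n_permutations = 10000) {
  x <- merge(dated, assignment, by = "pair_id")
  x <- x[!is.na(x$T_years), ]
  strata <- sort(unique(x$stratum))
  summ <- do.call(rbind, lapply(strata, function(s) {
    xi <- x[x$stratum == s, ]
    data.frame(stratum = s, n = nrow(xi),
               mean_T = mean(xi$T_years), median_T = stats::median(xi$T_years),
               mean_ka_ks = mean(xi$ka_ks, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  comps <- NULL
  if (length(strata) >= 2) {
    prs <- utils::combn(strata, 2, simplify = FALSE)
    comps <- do.call(rbind, lapply(prs, function(pr) {
      a <- x$T_years[x$stratum == pr[1]]
      b <- x$T_years[x$stratum == pr[2]]
      p <- if (length(a) >= 2 && length(b) >= 2) {
        permutation_p(a, b, n_permutations)
      } else NA_real_
      data.frame(stratum_a = pr[1], stratum_b = pr[2], p_value = p,
                 stringsAsFactors = FALSE)
    }))
  }
  list(summary = summ, comparisons = comps)
}

## two-sample permutation test on |difference of means|
permutation_p <- function(a, b, n_perm = 10000) {
  obs <- abs(mean(a) - mean(b))
  pooled <- c(a, b)
  na <- length(a)
  hits <- 0
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), na)
    stat <- abs(mean(pooled[idx]) - mean(pooled[-idx]))
    if (stat >= obs - 1e-15) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}

#' Read paired FASTA alignments
#'
#' Two records per pair; records sharing the id prefix before the last
#' underscore-delimited token form a pair (e.g. `g001_X` / `g001_Y`).
#'
#' @param path FASTA file.
#' @return Named list of two-element character vectors.
#' @export
read_pair_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- names(seqs)
  prefix <- sub("_[^_]*$", "", ids)
  out <- lapply(split(seq_along(ids), prefix), function(i) {
    if (length(i) != 2) stop("read_pair_fasta: pair '", prefix[i[1]],
                             "' does not have exactly 2 records")
    as.character(seqs[i])
  })
  out[unique(prefix)]
}

#' Write paired sequences as FASTA
#' @param pairs named list of two-element character vectors.
#' @param path output path.
#' @param suffixes record-name suffixes for the two members.
#' @export
write_pair_fasta <- function(pairs, path, suffixes = c("X", "Y")) {
  lines <- unlist(lapply(names(pairs), function(id) {
    c(paste0(">", id, "_", suffixes[1]), pairs[[id]][[1]],
      paste0(">", id, "_", suffixes[2]), pairs[[id]][[2]])
  }))
  writeLines(lines, path)
  invisible(path)
}
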