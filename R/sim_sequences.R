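#' Simulate codon-aligned pairs at target Ka and Ks
#'
#' Starts from a random stop-free codon sequence, computes its NG86
#' synonymous (`S`) and nonsynonymous (`N`) site counts, and applies
#' Poisson-distributed numbers of single-nucleotide changes — synonymous
#' changes with mean `ps * S` and nonsynonymous with mean `pn * N`, where
#' `ps`/`pn` invert the Jukes-Cantor correction of the targets — each at a
#' distinct random codon. NG86 estimates on the resulting pairs converge to
#' the targets as `n_codons` grows.
#'
#' @param n_pairs number of pairs.
#' @param target_ks,target_ka target corrected rates (each must imply an
#'   uncorrected proportion below 3/4).
#' @param n_codons codons per sequence.
#' @param seed integer seed.
#' @return Named list of two-element character vectors (`pair_id` ->
#'   `c(seq1, seq2)`).
#' @export
simulate_sequence_pairs <- function(n_pairs, target_ks, target_ka = target_ks / 5,
                                    n_codons = 5000, seed = 1) {
  if (target_ks < 0 || target_ka < 0) stop("targets must be non-negative")
  ps <- 3 / 4 * (1 - exp(-4 / 3 * target_ks))
  pn <- 3 / 4 * (1 - exp(-4 / 3 * target_ka))
  if (ps >= 3 / 4 || pn >= 3 / 4) stop("infeasible targets (saturated)")
  set.seed(seed)
  tb <- ng86_tables()
  sense <- tb$codons[!tb$is_stop]
  # codons offering at least one synonymous / nonsynonymous one-step change
  has_syn <- vapply(sense, function(cd) nrow(one_step_changes(cd, TRUE)) > 0,
                    logical(1))
  pairs <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    anc <- sample(sense, n_codons, replace = TRUE)
    S <- sum(tb$syn_sites[anc])
    N <- 3 * n_codons - S
    n_syn <- stats::rpois(1, ps * S)
    n_non <- stats::rpois(1, pn * N)
    der <- anc
    syn_ok <- which(has_syn[anc])
    pick_syn <- sample(syn_ok, min(n_syn, length(syn_ok)))
    for (i in pick_syn) der[i] <- apply_change(der[i], syn = TRUE)
    remaining <- setdiff(seq_len(n_codons), pick_syn)
    pick_non <- sample(remaining, min(n_non, length(remaining)))
    for (i in pick_non) der[i] <- apply_change(der[i], syn = FALSE)
    pairs[[k]] <- c(paste(anc, collapse = ""), paste(der, collapse = ""))
  }
  names(pairs) <- sprintf("pair%03d", seq_len(n_pairs))
  pairs
}

## internal: one-step neighbors of a codon, split by synonymy; stop-codon
## targets excluded
one_step_changes <- function(codon, syn) {
  tb <- ng86_tables()
  cs <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (i in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), cs[i])) {
      nb <- cs; nb[i] <- b
      nb <- paste(nb, collapse = "")
      if (tb$is_stop[nb]) next
      if ((tb$aa[nb] == tb$aa[codon]) == syn) out <- c(out, nb)
    }
  }
  data.frame(codon = out, stringsAsFactors = FALSE)
}

apply_change <- function(codon, syn) {
  opts <- one_step_changes(codon, syn)$codon
  if (!length(opts)) return(codon)
  if (length(opts) == 1) opts else sample(opts, 1)
}

#' Simulate LTR-style pairs at a target K2P distance
#'
#' Solves for per-site transition (`P`) and transversion (`Q`) probabilities
#' with a 2:1 transition bias whose K2P distance equals the target, then
#' mutates a random sequence site-wise.
#'
#' @param n_pairs number of pairs.
#' @param target_k target K2P distance.
#' @param length_bp sequence length.
#' @param seed integer seed.
#' @return Named list of two-element character vectors.
#' @export
simulate_ltr_pairs <- function(n_pairs, target_k, length_bp = 1e4, seed = 1) {
  if (target_k < 0) stop("target_k must be non-negative")
  set.seed(seed)
  if (target_k == 0) {
    P <- 0; Q <- 0
  } else {
    f <- function(q) -0.5 * log(1 - 5 * q) - 0.25 * log(1 - 2 * q) - target_k
    qmax <- 0.2 - 1e-9
    if (f(qmax) < 0) stop("infeasible target_k (saturated)")
    Q <- stats::uniroot(f, c(1e-12, qmax), tol = 1e-14)$root
    P <- 2 * Q
  }
  bases <- c("A", "C", "G", "T")
  transit <- c(A = "G", G = "A", C = "T", T = "C")
  transver <- list(A = c("C", "T"), G = c("C", "T"),
                   C = c("A", "G"), T = c("A", "G"))
  pairs <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    a <- sample(bases, length_bp, replace = TRUE)
    b <- a
    u <- stats::runif(length_bp)
    ti <- u < P
    tv <- !ti & u < P + Q
    b[ti] <- transit[a[ti]]
    if (any(tv)) {
      b[tv] <- vapply(a[tv], function(x) sample(transver[[x]], 1), character(1))
    }
    pairs[[k]] <- c(paste(a, collapse = ""), paste(b, collapse = ""))
  }
  names(pairs) <- sprintf("ltr%03d", seq_len(n_pairs))
  pairs
}
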