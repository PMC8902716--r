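#' Per-site nucleotide diversity
#'
#' Mean pairwise difference among sampled chromosomes at one biallelic site:
#' `2 * c1 * (n - c1) / (n * (n - 1))` for `c1` alternate alleles among `n`
#' called alleles. Vectorized over sites.
#'
#' @param alt_count alternate allele count(s) `c1`.
#' @param called_alleles called allele count(s) `n`.
#' @return Per-site pi; `NA` where `n < 2`.
#' @examples
#' site_pi(2, 4)  # 4 of 6 haplotype pairs differ -> 2/3
#' @export
site_pi <- function(alt_count, called_alleles) {
  ifelse(called_alleles >= 2,
         2 * alt_count * (called_alleles - alt_count) /
           (called_alleles * (called_alleles - 1)),
         NA_real_)
}

#' Per-sample heterozygosity rate
#'
#' Fraction of called genotypes that are heterozygous, per sample.
#'
#' @param sites a [site_table()].
#' @param samples sample ids (default: all).
#' @return Named numeric vector; `NA` for samples with no called genotype.
#' @export
het_rate <- function(sites, samples = sites$samples) {
  G <- geno_of(sites, samples)
  het <- colSums(G == 1, na.rm = TRUE)
  called <- colSums(!is.na(G))
  ifelse(called > 0, het / called, NA_real_)
}

#' Folded site frequency spectrum
#'
#' Tallies polymorphic sites by minor-allele count class `k = min(c1, n-c1)`,
#' `k = 1..floor(n/2)`. Sites with missing data use their own called-allele
#' count and are projected onto the full-data classes by rounding their minor
#' allele frequency to the nearest class of the maximum `n` observed.
#'
#' @param sites a [site_table()].
#' @param samples sample ids defining the population.
#' @return Integer vector of class counts, names `1..floor(n_max/2)`.
#' @export
folded_sfs <- function(sites, samples) {
  G <- geno_of(sites, samples)
  cc <- allele_counts(G)
  if (max(cc$n) < 2) stop("folded_sfs: fewer than 2 called chromosomes")
  k <- folded_class(cc$alt, cc$n, max(cc$n))
  n_max <- max(cc$n)
  kmax <- floor(n_max / 2)
  tab <- tabulate(k[!is.na(k)], nbins = kmax)
  stats::setNames(tab, seq_len(kmax))
}

## internal: folded frequency class per site (NA for monomorphic / uncalled)
folded_class <- function(alt, n, n_max) {
  minor <- pmin(alt, n - alt)
  k <- ifelse(n == n_max, minor, round(minor / pmax(n, 1) * n_max))
  k[minor == 0 | n < 2] <- NA
  k <- pmin(k, floor(n_max / 2))
  k[!is.na(k) & k < 1] <- 1  # polymorphic sites projected below class 1 stay rare
  k
}

#' Per-site sex association scan
#'
#' Allelic chi-square test of allele counts against sex (2x2 table, 1 df, no
#' continuity correction), reported as `-log10(P)`. Sites with a zero margin
#' (monomorphic, or a sex with no called alleles) score 0. A deliberate
#' simplification of mixed-model association: the SDR scan needs a per-site
#' ranking of sex linkage, not kinship correction. An optional
#' genomic-control rescaling (`lambda`) divides the chi-square statistics by
#' the ratio of their median to 0.4549 (the null median of a 1-df
#' chi-square) before conversion, for use on stratified populations.
#'
#' @param sites a [site_table()].
#' @param sheet a [sample_sheet()]; samples with sex `U` are ignored.
#' @param genomic_control apply the lambda rescaling?
#' @return A data frame `chrom`, `pos`, `chisq`, `assoc_score`.
#' @export
sex_association_scan <- function(sites, sheet, genomic_control = FALSE) {
  males <- intersect(sheet_samples(sheet, sex = "M"), sites$samples)
  females <- intersect(sheet_samples(sheet, sex = "F"), sites$samples)
  if (length(males) < 2 || length(females) < 2) {
    stop("sex_association_scan: need at least 2 samples of each sex")
  }
  cm <- allele_counts(geno_of(sites, males))
  cf <- allele_counts(geno_of(sites, females))
  a <- cm$alt; b <- cm$n - cm$alt   # male alt / ref alleles
  c <- cf$alt; d <- cf$n - cf$alt   # female alt / ref alleles
  N <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chisq <- ifelse(denom > 0, N * (a * d - b * c)^2 / denom, 0)
  if (genomic_control) {
    lambda <- stats::median(chisq[chisq > 0]) / stats::qchisq(0.5, df = 1)
    if (is.finite(lambda) && lambda > 1) chisq <- chisq / lambda
  }
  score <- ifelse(chisq > 0,
                  -stats::pchisq(chisq, df = 1, lower.tail = FALSE,
                                 log.p = TRUE) / log(10),
                  0)
  data.frame(chrom = sites$chrom, pos = sites$pos, chisq = chisq,
             assoc_score = score, stringsAsFactors = FALSE)
}

#' Flag male-specific SNPs
#'
#' A site is male-specific when the alternate allele is carried (dosage >= 1)
#' by at least `min_male_carrier_frac` of genotyped males, by no genotyped
#' female, and both sexes are genotyped in at least `min_called_frac` of
#' their samples. The population-data analogue of Y-hemizygous markers.
#'
#' @param sites a [site_table()].
#' @param sheet a [sample_sheet()].
#' @param min_male_carrier_frac minimum carrier fraction among genotyped
#'   males (boundary passes).
#' @param min_called_frac minimum genotyped fraction per sex.
#' @return Logical vector, one flag per site.
#' @export
flag_male_specific <- function(sites, sheet, min_male_carrier_frac = 0.90,
                               min_called_frac = 0.80) {
  males <- intersect(sheet_samples(sheet, sex = "M"), sites$samples)
  females <- intersect(sheet_samples(sheet, sex = "F"), sites$samples)
  Gm <- geno_of(sites, males); Gf <- geno_of(sites, females)
  m_called <- rowSums(!is.na(Gm)); f_called <- rowSums(!is.na(Gf))
  m_carrier <- rowSums(Gm >= 1, na.rm = TRUE)
  f_carrier <- rowSums(Gf >= 1, na.rm = TRUE)
  m_called > 0 & f_called > 0 &
    m_carrier >= min_male_carrier_frac * m_called &
    f_carrier == 0 &
    m_called >= min_called_frac * length(males) &
    f_called >= min_called_frac * length(females)
}

#' Flag sex co-segregating SNPs and contigs
#'
#' In an F1 cross, a site co-segregates with sex when the father is
#' heterozygous, the mother lacks the father-specific allele, and carrying
#' that allele coincides with being male across all genotyped offspring, up
#' to `mismatch_tolerance` exceptions. Contigs containing at least `min_snps`
#' co-segregating sites are the sex co-segregation contigs.
#'
#' @param sites a [site_table()] of the F1 family (parents + offspring).
#' @param sheet a [sample_sheet()] with one `parent_female`, one
#'   `parent_male`, and `F1` offspring.
#' @param contigs a [contig_map()].
#' @param min_snps minimum co-segregating SNPs per selected contig
#'   (default 4).
#' @param mismatch_tolerance offspring allowed to contradict the pattern
#'   (default 0).
#' @return A list with `coseg` (per-site logical), `contigs` (character
#'   vector of co-segregating contig ids), and `contig_counts` (data frame of
#'   per-contig co-segregating SNP counts).
#' @export
flag_coseg_and_contigs <- function(sites, sheet, contigs, min_snps = 4,
                                   mismatch_tolerance = 0) {
  father <- sheet_samples(sheet, role = "parent_male")
  mother <- sheet_samples(sheet, role = "parent_female")
  kids <- sheet_samples(sheet, role = "F1")
  if (length(father) != 1 || length(mother) != 1) {
    stop("flag_coseg_and_contigs: need exactly one parent of each sex")
  }
  gF <- as.vector(geno_of(sites, father))
  gM <- as.vector(geno_of(sites, mother))
  Gk <- geno_of(sites, kids)
  kid_male <- sheet$sex[match(kids, sheet$sample_id)] == "M"

  # father-specific allele: the allele the heterozygous father carries and
  # the mother does not (alt when mother is 0/0, ref when mother is 1/1)
  f_het <- !is.na(gF) & gF == 1L
  alt_specific <- f_het & !is.na(gM) & gM == 0L
  ref_specific <- f_het & !is.na(gM) & gM == 2L
  coseg <- rep(FALSE, n_sites(sites))
  for (mode in c("alt", "ref")) {
    idx <- which(if (mode == "alt") alt_specific else ref_specific)
    if (!length(idx)) next
    Gi <- Gk[idx, , drop = FALSE]
    carrier <- if (mode == "alt") Gi >= 1L else Gi <= 1L
    mism <- carrier != matrix(kid_male, nrow(Gi), ncol(Gi), byrow = TRUE)
    n_called <- rowSums(!is.na(Gi))
    n_mism <- rowSums(mism, na.rm = TRUE)
    coseg[idx] <- n_called > 0 & n_mism <= mismatch_tolerance
  }
  cidx <- contig_at(contigs, sites$chrom, sites$pos - 1)
  counts <- table(factor(cidx[coseg], levels = seq_len(nrow(contigs))))
  contig_counts <- data.frame(contig_id = contigs$contig_id,
                              n_coseg = as.integer(counts),
                              stringsAsFactors = FALSE)
  list(coseg = coseg,
       contigs = contigs$contig_id[contig_counts$n_coseg >= min_snps],
       contig_counts = contig_counts)
}
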