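#' Site tables
#'
#' A `site_table` holds biallelic SNPs as a genotype dosage matrix: one row
#' per site, one column per sample, entries 0/1/2 = copies of the alternate
#' allele, `NA` = missing. Positions are 1-based (VCF convention) and strictly
#' increasing within a chromosome. Every per-site and windowed statistic in
#' the package operates on this container.
#'
#' @param chrom,pos,ref,alt per-site vectors; `pos` 1-based.
#' @param geno integer matrix (sites x samples) with values in
#'   \{0, 1, 2, NA\}; column names are sample ids.
#' @return An object of class `site_table`: a list with fields `chrom`,
#'   `pos`, `ref`, `alt`, `geno`, `samples`.
#' @export
site_table <- function(chrom, pos, ref, alt, geno) {
  geno <- as.matrix(geno)
  stopifnot(length(chrom) == nrow(geno), length(pos) == nrow(geno),
            length(ref) == nrow(geno), length(alt) == nrow(geno))
  if (is.null(colnames(geno))) stop("site_table: geno must have sample column names")
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("site_table: genotype dosages must be 0, 1, 2 or NA")
  }
  ord <- order(chrom, pos)
  chrom <- as.character(chrom)[ord]; pos <- as.integer(pos)[ord]
  ref <- as.character(ref)[ord]; alt <- as.character(alt)[ord]
  geno <- geno[ord, , drop = FALSE]
  dup <- duplicated(paste(chrom, pos))
  if (any(dup)) stop("site_table: duplicated positions within a chromosome")
  x <- list(chrom = chrom, pos = pos, ref = ref, alt = alt,
            geno = geno, samples = colnames(geno))
  class(x) <- "site_table"
  x
}

#' @export
print.site_table <- function(x, ...) {
  cat(sprintf("<site_table> %d sites x %d samples on %d chromosome(s)\n",
              n_sites(x), length(x$samples), length(unique(x$chrom))))
  invisible(x)
}

#' Number of sites in a site table
#' @param sites a `site_table`.
#' @export
n_sites <- function(sites) length(sites$pos)

#' Subset a site table
#' @param sites a `site_table`.
#' @param i site index (logical or integer); `NULL` keeps all.
#' @param samples character vector of sample ids; `NULL` keeps all.
#' @return A `site_table`.
#' @export
subset_sites <- function(sites, i = NULL, samples = NULL) {
  if (is.null(i)) i <- seq_along(sites$pos)
  j <- if (is.null(samples)) sites$samples else samples
  miss <- setdiff(j, sites$samples)
  if (length(miss)) stop("subset_sites: unknown samples: ", paste(miss, collapse = ", "))
  site_table(sites$chrom[i], sites$pos[i], sites$ref[i], sites$alt[i],
             sites$geno[i, j, drop = FALSE])
}

## internal: dosage submatrix for a set of sample ids
geno_of <- function(sites, samples) {
  miss <- setdiff(samples, sites$samples)
  if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
  sites$geno[, samples, drop = FALSE]
}

## internal: per-site alt allele count and called allele count
allele_counts <- function(G) {
  called <- rowSums(!is.na(G))
  list(alt = rowSums(G, na.rm = TRUE), n = 2L * called, n_samples = called)
}

#' Read a VCF into a site table
#'
#' Reads a VCF (v4.2, `GT` genotypes) keeping only biallelic SNPs, then
#' applies the standard population filters: per-site missingness at most
#' `max_missing` and folded minor allele frequency at least `min_maf`
#' (boundary values are retained in both cases). Multiallelic and non-SNP
#' records are skipped and counted.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param sheet a [sample_sheet()]; its samples must all be present in the
#'   VCF, and only they are read.
#' @param max_missing maximum fraction of missing genotypes per site
#'   (default 0.20).
#' @param min_maf minimum minor allele frequency (default 0.05). Set to 0 to
#'   disable (monomorphic sites are then retained).
#' @return A [site_table()] with attribute `n_skipped` (records dropped as
#'   multiallelic/non-SNP) and `n_filtered` (sites failing the filters).
#' @export
read_vcf <- function(path, sheet, max_missing = 0.20, min_maf = 0.05) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- vcf@gt
  if (is.null(fmt) || ncol(fmt) < 2) stop("read_vcf: VCF has no genotype columns")
  fmt_keys <- strsplit(fmt[, 1], ":", fixed = TRUE)
  if (!all(vapply(fmt_keys, function(k) "GT" %in% k, logical(1)))) {
    stop("read_vcf: FORMAT lacks a GT field")
  }
  vcf_samples <- colnames(fmt)[-1]
  missing_samp <- setdiff(sheet$sample_id, vcf_samples)
  if (length(missing_samp)) {
    stop("read_vcf: sample sheet samples absent from VCF: ",
         paste(missing_samp, collapse = ", "))
  }
  fix <- vcf@fix
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  nucs <- c("A", "C", "G", "T")
  snp <- ref %in% nucs & alt %in% nucs
  n_skipped <- sum(!snp)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[snp, sheet$sample_id, drop = FALSE]
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  dos <- (a1 == "1") + (a2 == "1")
  dos[a1 == "." | a2 == "." | is.na(gt)] <- NA
  dos <- matrix(as.integer(dos), nrow = nrow(gt),
                dimnames = list(NULL, sheet$sample_id))
  chrom <- fix[snp, "CHROM"]; pos <- as.integer(fix[snp, "POS"])
  cc <- allele_counts(dos)
  miss_frac <- 1 - cc$n_samples / ncol(dos)
  maf <- ifelse(cc$n > 0, pmin(cc$alt, cc$n - cc$alt) / cc$n, 0)
  keep <- miss_frac <= max_missing & maf >= min_maf
  st <- site_table(chrom[keep], pos[keep], ref[snp][keep], alt[snp][keep],
                   dos[keep, , drop = FALSE])
  attr(st, "n_skipped") <- n_skipped
  attr(st, "n_filtered") <- sum(!keep)
  st
}

#' Write a site table as VCF v4.2
#'
#' Emits unphased diploid GT-only records; the inverse of [read_vcf()] with
#' filters disabled.
#'
#' @param sites a [site_table()].
#' @param path output path (`.vcf`).
#' @param contig_lengths optional named vector for `##contig` header lines.
#' @export
write_vcf <- function(sites, path, contig_lengths = NULL) {
  codes <- c("0/0", "0/1", "1/1")
  G <- sites$geno
  gt <- matrix("./.", nrow = nrow(G), ncol = ncol(G))
  ok <- !is.na(G)
  gt[ok] <- codes[G[ok] + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=dioscan",
    if (!is.null(contig_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths))
    },
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sites$samples), collapse = "\t")
  )
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
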