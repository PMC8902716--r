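#' Simulation configuration
#'
#' Defines the labeled synthetic datasets the pipeline is tested on: a
#' neutral-SFS autosomal background with Balding-Nichols population
#' divergence, and optional truth regions — a non-recombining Y-linked SDR
#' (males hemizygous carriers), a low-diversity sweep in designated
#' cultivated groups, and an admixture region where recipient haplotypes
#' carry donor-frequency draws.
#'
#' @param populations data frame with columns `name`, `size` (diploids),
#'   `sex_ratio` (fraction male), `fst` (Balding-Nichols divergence
#'   parameter, 0 < F < 1).
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param snp_per_kb background SNP density (sites per kb).
#' @param sdr_region,sweep_region,introgression_region `NULL` or a list
#'   `(chrom, start, end)` in 0-based half-open coordinates. Regions on one
#'   chromosome must not overlap.
#' @param y_marker_density Y-linked marker sites per kb inside `sdr_region`.
#' @param sweep_strength fraction of sweep-region sites whose cultivated
#'   allele frequency is driven to near-fixation.
#' @param cultivated character vector of population names treated as
#'   cultivated (sweep recipients).
#' @param quartet `NULL` or a list with entries `P1`, `P2`, `P3`, `O` naming
#'   populations for the four-taxon design; `P2` receives introgression from
#'   `P3`, `O` is held ancestral.
#' @param gamma per-haplotype probability that a `P2` haplotype carries a
#'   donor-frequency draw inside `introgression_region`.
#' @param outgroup_poly fraction of sites at which the outgroup retains
#'   residual polymorphism.
#' @param contig_meanlog,contig_sdlog,contig_min lognormal contig-length
#'   distribution (bp) for the simulated contig map.
#' @param seed mandatory integer seed; identical configurations and seeds
#'   give byte-identical outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(populations = data.frame(
                         name = "pop1", size = 60, sex_ratio = 0.5, fst = 0.1,
                         stringsAsFactors = FALSE),
                       chrom_lengths = c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7),
                       snp_per_kb = 2,
                       sdr_region = list(chrom = "chr1", start = 4e6, end = 6e6),
                       sweep_region = NULL,
                       introgression_region = NULL,
                       y_marker_density = 0.2,
                       sweep_strength = 0.95,
                       cultivated = character(),
                       quartet = NULL,
                       gamma = 0.3,
                       outgroup_poly = 0.01,
                       contig_meanlog = log(2.5e5), contig_sdlog = 0.45,
                       contig_min = 5e4,
                       seed = NULL) {
  if (is.null(seed)) stop("sim_config: a seed is mandatory")
  cfg <- list(populations = populations, chrom_lengths = chrom_lengths,
              snp_per_kb = snp_per_kb, sdr_region = sdr_region,
              sweep_region = sweep_region,
              introgression_region = introgression_region,
              y_marker_density = y_marker_density,
              sweep_strength = sweep_strength, cultivated = cultivated,
              quartet = quartet, gamma = gamma, outgroup_poly = outgroup_poly,
              contig_meanlog = contig_meanlog, contig_sdlog = contig_sdlog,
              contig_min = contig_min, seed = as.integer(seed))
  stopifnot(all(cfg$populations$fst > 0 & cfg$populations$fst < 1),
            cfg$gamma >= 0, cfg$gamma <= 1)
  regions <- Filter(Negate(is.null),
                    list(sdr = sdr_region, sweep = sweep_region,
                         introgression = introgression_region))
  for (r in regions) {
    if (!r$chrom %in% names(chrom_lengths) ||
        r$start < 0 || r$end > chrom_lengths[[r$chrom]] || r$start >= r$end) {
      stop("sim_config: truth region outside chromosome bounds")
    }
  }
  if (length(regions) > 1) {
    labs <- names(regions)
    iv <- data.frame(chrom = vapply(regions, `[[`, "", "chrom"),
                     start = vapply(regions, `[[`, 0, "start"),
                     end = vapply(regions, `[[`, 0, "end"))
    for (chr in unique(iv$chrom)) {
      xi <- iv[iv$chrom == chr, ]
      xi <- xi[order(xi$start), ]
      if (nrow(xi) > 1 && any(xi$start[-1] < xi$end[-nrow(xi)])) {
        stop("sim_config: overlapping truth regions on ", chr)
      }
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

## internal: ancestral derived-allele frequency with density proportional to
## 1/x on [1/(2N), 1 - 1/(2N)] (neutral SFS), via inverse-CDF sampling
rneutral_freq <- function(n, N) {
  a <- 1 / (2 * N)
  a * ((1 - a) / a)^stats::runif(n)
}

## internal: Balding-Nichols population frequency given ancestral x and F
rbn_freq <- function(x, F) {
  stats::rbeta(length(x), x * (1 - F) / F, (1 - x) * (1 - F) / F)
}

## internal: truth regions as a labeled interval data frame
truth_regions <- function(cfg) {
  regs <- Filter(Negate(is.null),
                 list(sdr = cfg$sdr_region, sweep = cfg$sweep_region,
                      introgression = cfg$introgression_region))
  if (!length(regs)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character()))
  }
  data.frame(chrom = vapply(regs, `[[`, "", "chrom"),
             start = vapply(regs, `[[`, 0, "start"),
             end = vapply(regs, `[[`, 0, "end"),
             name = names(regs), stringsAsFactors = FALSE)
}

in_region <- function(chrom, pos1, region) {
  if (is.null(region)) return(rep(FALSE, length(pos1)))
  chrom == region$chrom & (pos1 - 1) >= region$start & (pos1 - 1) < region$end
}

#' Simulate a structured dioecious population
#'
#' Draws per-site ancestral derived-allele frequencies from the neutral
#' spectrum, diverges them into per-population frequencies under the
#' Balding-Nichols model, and samples Hardy-Weinberg genotypes. Truth
#' structure is then overlaid: Y-linked marker sites inside `sdr_region`
#' (every male heterozygous, every female ancestral), near-fixation allele
#' frequencies for cultivated groups inside `sweep_region`, donor-copied
#' haplotypes for the quartet's `P2` inside `introgression_region`, and an
#' outgroup held at the ancestral allele apart from residual polymorphism.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional directory; when given, writes `population.vcf`,
#'   `samples.tsv`, `contigs.tsv`, `truth.bed` and `truth_sites.tsv`.
#' @return A list with `sites` ([site_table()]), `sheet`, `contigs`, `truth`
#'   (list of `regions` and `y_markers`), `chrom_lengths`, and file `paths`
#'   when `out_dir` was given.
#' @export
simulate_population <- function(cfg, out_dir = NULL) {
  set.seed(cfg$seed)
  pops <- cfg$populations
  N <- sum(pops$size)

  # sample sheet: deterministic sex blocks per population
  ids <- character(0); grp <- character(0); sex <- character(0)
  for (i in seq_len(nrow(pops))) {
    n <- pops$size[i]
    n_m <- round(n * pops$sex_ratio[i])
    s <- c(rep("M", n_m), rep("F", n - n_m))
    ids <- c(ids, sprintf("%s_%s%02d", pops$name[i], s, seq_len(n)))
    grp <- c(grp, rep(pops$name[i], n))
    sex <- c(sex, s)
  }
  sheet <- sample_sheet(ids, grp, sex, role = "natural")

  # background site positions
  chrom <- character(0); pos <- integer(0)
  for (chr in names(cfg$chrom_lengths)) {
    len <- cfg$chrom_lengths[[chr]]
    n_bg <- round(len / 1000 * cfg$snp_per_kb)
    p <- sort(sample.int(len, n_bg))
    chrom <- c(chrom, rep(chr, n_bg)); pos <- c(pos, p)
  }
  S <- length(pos)
  x <- rneutral_freq(S, N)

  out_name <- if (!is.null(cfg$quartet)) cfg$quartet$O else NULL
  pfreq <- matrix(NA_real_, nrow = S, ncol = nrow(pops),
                  dimnames = list(NULL, pops$name))
  for (i in seq_len(nrow(pops))) pfreq[, i] <- rbn_freq(x, pops$fst[i])

  # outgroup: ancestral except residual polymorphism
  if (!is.null(out_name)) {
    po <- numeric(S)
    res <- stats::runif(S) < cfg$outgroup_poly
    po[res] <- stats::rbeta(sum(res), 1, 9)
    pfreq[, out_name] <- po
  }

  # sweep: cultivated frequencies driven to near-fixation
  if (!is.null(cfg$sweep_region) && length(cfg$cultivated)) {
    swp <- which(in_region(chrom, pos, cfg$sweep_region))
    hit <- swp[stats::runif(length(swp)) < cfg$sweep_strength]
    for (g in cfg$cultivated) {
      eps <- stats::rbeta(length(hit), 0.2, 3.8)
      pfreq[hit, g] <- ifelse(pfreq[hit, g] >= 0.5, 1 - eps, eps)
    }
  }

  geno <- matrix(NA_integer_, nrow = S, ncol = N, dimnames = list(NULL, ids))
  for (i in seq_len(nrow(pops))) {
    cols <- which(grp == pops$name[i])
    # rbinom recycles the frequency vector over columns (column-major)
    geno[, cols] <- stats::rbinom(S * length(cols), 2, pfreq[, i])
  }

  # introgression: P2 haplotypes carry donor-frequency draws with prob gamma
  if (!is.null(cfg$introgression_region) && !is.null(cfg$quartet) &&
      cfg$gamma > 0) {
    reg <- which(in_region(chrom, pos, cfg$introgression_region))
    if (length(reg)) {
      p2cols <- which(grp == cfg$quartet$P2)
      p3 <- pfreq[reg, cfg$quartet$P3]
      p2 <- pfreq[reg, cfg$quartet$P2]
      for (j in p2cols) {
        h <- matrix(0L, length(reg), 2)
        for (k in 1:2) {
          donor <- stats::runif(length(reg)) < cfg$gamma
          psel <- ifelse(donor, p3, p2)
          h[, k] <- stats::rbinom(length(reg), 1, psel)
        }
        geno[reg, j] <- h[, 1] + h[, 2]
      }
    }
  }

  # Y-linked marker sites inside the SDR: het in every male, absent in females
  y_markers <- data.frame(chrom = character(), pos = integer())
  if (!is.null(cfg$sdr_region) && cfg$y_marker_density > 0) {
    r <- cfg$sdr_region
    n_y <- round((r$end - r$start) / 1000 * cfg$y_marker_density)
    ypos <- r$start + sort(sample.int(r$end - r$start, n_y))  # 1-based
    ypos <- setdiff(ypos, pos[chrom == r$chrom])
    yg <- matrix(0L, length(ypos), N, dimnames = list(NULL, ids))
    yg[, sex == "M"] <- 1L
    chrom <- c(chrom, rep(r$chrom, length(ypos)))
    pos <- c(pos, ypos)
    geno <- rbind(geno, yg)
    y_markers <- data.frame(chrom = r$chrom, pos = ypos,
                            stringsAsFactors = FALSE)
  }

  ra <- sim_ref_alt(length(pos))
  sites <- site_table(chrom, pos, ra$ref, ra$alt, geno)

  contigs <- simulate_contig_map(cfg)
  truth <- list(regions = truth_regions(cfg), y_markers = y_markers)
  out <- list(sites = sites, sheet = sheet, contigs = contigs, truth = truth,
              chrom_lengths = cfg$chrom_lengths)
  if (!is.null(out_dir)) out$paths <- write_simulation(out, out_dir)
  out
}

## internal: uniform random REF base and a distinct ALT base per site
sim_ref_alt <- function(S) {
  bases <- c("A", "C", "G", "T")
  ri <- sample.int(4, S, replace = TRUE)
  off <- sample.int(3, S, replace = TRUE)
  list(ref = bases[ri], alt = bases[(ri - 1 + off) %% 4 + 1])
}

## internal: random contig tiling of each chromosome
simulate_contig_map <- function(cfg) {
  id <- character(0); cc <- character(0); st <- numeric(0); en <- numeric(0)
  k <- 0
  for (chr in names(cfg$chrom_lengths)) {
    len <- cfg$chrom_lengths[[chr]]
    at <- 0
    while (at < len) {
      k <- k + 1
      clen <- max(cfg$contig_min,
                  round(stats::rlnorm(1, cfg$contig_meanlog, cfg$contig_sdlog)))
      end <- min(at + clen, len)
      id <- c(id, sprintf("tig%05d", k))
      cc <- c(cc, chr); st <- c(st, at); en <- c(en, end)
      at <- end
    }
  }
  ori <- sample(c("+", "-"), length(id), replace = TRUE)
  contig_map(id, cc, st, en, ori)
}

#' Write a simulated dataset to disk
#' @param sim result of [simulate_population()] or [simulate_f1_cross()].
#' @param out_dir output directory (created if needed).
#' @return Named list of file paths.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    vcf = file.path(out_dir, "population.vcf"),
    sheet = file.path(out_dir, "samples.tsv"),
    truth_bed = file.path(out_dir, "truth.bed"),
    truth_sites = file.path(out_dir, "truth_sites.tsv")
  )
  write_vcf(sim$sites, paths$vcf, contig_lengths = sim$chrom_lengths)
  write_sample_sheet(sim$sheet, paths$sheet)
  if (!is.null(sim$contigs)) {
    paths$contigs <- file.path(out_dir, "contigs.tsv")
    write_contig_map(sim$contigs, paths$contigs)
  }
  write_bed(sim$truth$regions, paths$truth_bed)
  site_labels <- NULL
  if (!is.null(sim$truth$y_markers) && nrow(sim$truth$y_markers)) {
    site_labels <- cbind(sim$truth$y_markers, label = "y_marker")
  }
  if (!is.null(sim$truth$coseg_sites) && nrow(sim$truth$coseg_sites)) {
    site_labels <- rbind(site_labels,
                         cbind(sim$truth$coseg_sites, label = "coseg_snp"))
  }
  if (is.null(site_labels)) {
    site_labels <- data.frame(chrom = character(), pos = integer(),
                              label = character())
  }
  utils::write.table(site_labels, paths$truth_sites, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}
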