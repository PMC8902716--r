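#' Pipeline configuration
#'
#' Collects every window size, step, cutoff and rate used across the scans,
#' defaulting to the published study design: co-segregation contig density in
#' 100-kb windows at the top 1%; sex association with a fixed -log10(P) >= 6
#' cutoff projected onto 20-kb windows; male-specific SNP density in 20-kb
#' windows at the top 1%; male/female Fst in 1000-kb windows at the top 5%;
#' male/female Tajima's D ratio in 200-kb windows at the top 5%; sweep scans
#' in 100-kb windows with 20-kb steps (top 1%, 2-kb flanks, 4-kb merge) plus
#' a folded-SFS GLR on a 20-kb grid; fd_M in 1-kb windows with 200-bp steps
#' (positive 95th-percentile outliers); and a substitution rate
#' r = 2.8e-9 per site per year for molecular dating.
#'
#' @param ... overrides for any default (unknown names are an error).
#' @return A list of class `dioscan_config`.
#' @export
dioscan_config <- function(...) {
  cfg <- list(
    # variant filters
    max_missing = 0.20,
    min_maf = 0.05,
    # SDR evidence tracks: window size / step / cutoff
    coseg_window = 1e5, coseg_step = 25e3, coseg_q = 0.01,
    coseg_min_snps = 4, coseg_mismatch_tolerance = 0,
    assoc_window = 20e3, assoc_step = 5e3, assoc_cutoff = 6,
    msnp_window = 20e3, msnp_step = 5e3, msnp_q = 0.01,
    msnp_min_male_carrier_frac = 0.90, msnp_min_called_frac = 0.80,
    fst_window = 1e6, fst_step = 1e6, fst_q = 0.05,
    tajima_window = 2e5, tajima_step = 5e4, tajima_q = 0.05,
    tajima_min_abs_female = 0.05,
    # clustering of passing windows into per-track spans for delimitation
    span_gap = 1e6,
    min_tracks = NULL,  # NULL = all available
    # diversity scan
    div_window = 50e3, div_step = 10e3,
    # sweep scan
    sweep_window = 1e5, sweep_step = 20e3, sweep_q = 0.01,
    sweep_flank = 2e3, sweep_merge_gap = 4e3,
    glr_grid = 20e3, glr_min_sites = 10, glr_q = 0.01,
    # introgression scan
    fdm_window = 1e3, fdm_step = 200, fdm_min_sites = 3, fdm_q = 0.05,
    jackknife_blocks = 100,
    # molecular dating
    rate = 2.8e-9,
    n_permutations = 10000,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "dioscan_config"
  cfg
}

#' @export
print.dioscan_config <- function(x, ...) {
  cat("<dioscan_config>\n")
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Serialize / restore a configuration as JSON
#' @param cfg a [dioscan_config()].
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(dioscan_config, x[!vapply(x, is.null, logical(1))])
}

#' @importFrom utils str
NULL
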