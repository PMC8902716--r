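#' Build the five SDR evidence tracks
#'
#' Computes, on their configured window grids, the five independent signals
#' of a non-recombining sex-determination region:
#' \describe{
#'   \item{coseg_density}{density of sex co-segregation contigs (F1 cross),
#'     100-kb windows, top 1% (requires `f1_sites`; skipped with a warning
#'     otherwise);}
#'   \item{assoc}{per-SNP sex-association `-log10(P)` projected onto 20-kb
#'     windows by maximum score, fixed cutoff 6;}
#'   \item{male_specific_density}{per-bp density of male-specific SNPs,
#'     20-kb windows, top 1%;}
#'   \item{fst}{male/female Weir-Cockerham Fst, 1000-kb windows, top 5%;}
#'   \item{tajima_ratio}{male/female Tajima's D ratio, 200-kb windows, top
#'     5%; windows with undefined D, `|D_female|` below
#'     `tajima_min_abs_female`, or oppositely signed D values are masked.}
#' }
#' Each track records its cutoff rule, realized cutoff, and the passing
#' windows merged with gap at most the window step.
#'
#' @param sites natural-population [site_table()].
#' @param sheet its [sample_sheet()] (both sexes required).
#' @param chrom_lengths named chromosome lengths.
#' @param cfg a [dioscan_config()].
#' @param f1_sites,f1_sheet optional F1-cross site table and sheet for the
#'   co-segregation track.
#' @param contigs [contig_map()] (required for the co-segregation track and
#'   for boundary snapping downstream).
#' @return A named list of evidence tracks; each has `name`, `windows` (with
#'   `value` and `pass`), `cutoff_rule`, `cutoff`, `passing`
#'   (an [interval_set()]).
#' @export
build_evidence_tracks <- function(sites, sheet, chrom_lengths,
                                  cfg = dioscan_config(),
                                  f1_sites = NULL, f1_sheet = NULL,
                                  contigs = NULL) {
  males <- sheet_samples(sheet, sex = "M", role = "natural")
  females <- sheet_samples(sheet, sex = "F", role = "natural")
  if (length(males) < 2) stop("build_evidence_tracks: no usable male samples")
  if (length(females) < 2) stop("build_evidence_tracks: no usable female samples")
  tracks <- list()

  # (1) sex co-segregation contig density (F1 linkage evidence)
  if (!is.null(f1_sites) && !is.null(f1_sheet) && !is.null(contigs)) {
    cs <- flag_coseg_and_contigs(f1_sites, f1_sheet, contigs,
                                 min_snps = cfg$coseg_min_snps,
                                 mismatch_tolerance = cfg$coseg_mismatch_tolerance)
    ctg <- contigs[contigs$contig_id %in% cs$contigs, , drop = FALSE]
    w <- make_windows(chrom_lengths, cfg$coseg_window, cfg$coseg_step)
    w <- windowed_density(ctg, w, normalize = FALSE)
    tracks$coseg_density <- finish_track("coseg_density", w,
                                         quantile_rule(cfg$coseg_q), cfg)
  } else {
    warning("co-segregation track skipped (no F1 data or contig map)")
  }

  # (2) sex association, fixed -log10(P) cutoff, max score per window
  assoc <- sex_association_scan(sites, sheet)
  w <- make_windows(chrom_lengths, cfg$assoc_window, cfg$assoc_step)
  w$value <- window_max(assoc$chrom, assoc$pos, assoc$assoc_score, w)
  tracks$assoc <- finish_track("assoc", w,
                               list(type = "fixed", cutoff = cfg$assoc_cutoff),
                               cfg)

  # (3) male-specific SNP density
  ms <- flag_male_specific(sites, sheet,
                           min_male_carrier_frac = cfg$msnp_min_male_carrier_frac,
                           min_called_frac = cfg$msnp_min_called_frac)
  w <- make_windows(chrom_lengths, cfg$msnp_window, cfg$msnp_step)
  w <- windowed_density(data.frame(chrom = sites$chrom[ms],
                                   pos = sites$pos[ms]), w, normalize = TRUE)
  tracks$male_specific_density <- finish_track("male_specific_density", w,
                                               quantile_rule(cfg$msnp_q), cfg)

  # (4) male/female Fst
  w <- make_windows(chrom_lengths, cfg$fst_window, cfg$fst_step)
  w <- window_fst(sites, females, males, w)
  w$value <- w$fst
  tracks$fst <- finish_track("fst", w, quantile_rule(cfg$fst_q), cfg)

  # (5) male/female Tajima's D ratio
  w <- make_windows(chrom_lengths, cfg$tajima_window, cfg$tajima_step)
  dm <- window_diversity(sites, males, w)$tajima_d
  df <- window_diversity(sites, females, w)$tajima_d
  usable <- !is.na(dm) & !is.na(df) & abs(df) >= cfg$tajima_min_abs_female &
    sign(dm) == sign(df)
  w$value <- ifelse(usable, dm / df, NA_real_)
  w$d_male <- dm
  w$d_female <- df
  tracks$tajima_ratio <- finish_track("tajima_ratio", w,
                                      quantile_rule(cfg$tajima_q), cfg)
  tracks
}

quantile_rule <- function(q) list(type = "quantile", q = q)

## internal: apply a cutoff rule to a windowed track and record passing
## windows (merged with gap <= step) and the span of the largest passing
## cluster (merged with gap <= span_gap), used for delimitation
finish_track <- function(name, windows, rule, cfg) {
  vals <- windows$value
  cutoff <- if (rule$type == "fixed") {
    rule$cutoff
  } else if (all(is.na(vals))) {
    NA_real_
  } else {
    threshold_by_quantile(vals, rule$q)
  }
  pass <- !is.na(vals) & !is.na(cutoff) & vals >= cutoff
  windows$pass <- pass
  step <- attr(windows, "step")
  passing <- if (any(pass)) {
    merge_intervals(interval_set(windows$chrom[pass], windows$start[pass],
                                 windows$end[pass]), max_gap = step)
  } else {
    interval_set()
  }
  span <- if (any(pass)) {
    clusters <- merge_intervals(passing, max_gap = cfg$span_gap)
    clusters[which.max(clusters$end - clusters$start), , drop = FALSE]
  } else {
    interval_set()
  }
  structure(list(name = name, windows = windows, cutoff_rule = rule,
                 cutoff = cutoff, passing = passing, span = span),
            class = "evidence_track")
}

#' @export
print.evidence_track <- function(x, ...) {
  cat(sprintf("<evidence_track> %s: cutoff %s, %d/%d windows passing\n",
              x$name, format(x$cutoff, digits = 4), sum(x$windows$pass),
              nrow(x$windows)))
  invisible(x)
}

## internal: max of per-site scores per window (NA-empty windows -> NA)
window_max <- function(chrom, pos, score, windows) {
  out <- rep(NA_real_, nrow(windows))
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos0 <- pos[ord] - 1; score <- score[ord]
  for (chr in unique(windows$chrom)) {
    wi <- which(windows$chrom == chr)
    si <- which(chrom == chr)
    if (!length(si)) next
    rng <- window_site_range(pos0[si], windows$start[wi], windows$end[wi])
    sc <- score[si]
    out[wi] <- vapply(seq_along(wi), function(j) {
      if (rng$i2[j] < rng$i1[j]) return(NA_real_)
      max(sc[rng$i1[j]:rng$i2[j]])
    }, numeric(1))
  }
  out
}

#' Delimit the sex-determination region
#'
#' Intersects the per-track intervals (the span of each track's largest
#' cluster of passing windows) across at least `min_tracks` tracks, takes
#' the longest interval of the intersection as the raw SDR, and snaps its
#' boundaries outward to the terminals of the contigs containing them (a
#' boundary falling between contigs snaps to the nearest inner contig
#' terminal). An empty intersection yields a no-call with per-track
#' diagnostics.
#'
#' @param tracks list of evidence tracks from [build_evidence_tracks()], or
#'   any list of objects with a `span` interval set (pre-thresholded
#'   intervals can be supplied as `list(span = interval_set(...))`).
#' @param contigs a [contig_map()] (optional; without it the raw interval is
#'   reported unsnapped).
#' @param min_tracks minimum tracks that must overlap (default: all
#'   supplied). With fewer than all tracks, the intersection is taken over
#'   every combination of `min_tracks` tracks and the longest resulting
#'   interval wins.
#' @return An object of class `sdr_call`: `called`, `chrom`, `raw_interval`,
#'   `snapped_interval`, `length_bp`, `track_intervals`, `snap_contigs`,
#'   `diagnostics`.
#' @export
delimit_sdr <- function(tracks, contigs = NULL, min_tracks = NULL) {
  spans <- lapply(tracks, function(t) as_interval_set(t$span))
  usable <- vapply(spans, nrow, integer(1)) > 0
  track_names <- names(spans)
  if (is.null(min_tracks)) min_tracks <- length(spans)
  min_tracks <- max(min_tracks, 1)
  if (sum(usable) < min_tracks) {
    return(no_call(spans, "fewer than the required number of non-empty tracks"))
  }
  use <- spans[usable]
  n_way_intersect <- function(sets) {
    if (length(sets) == 1) sets[[1]] else intersect_interval_sets(sets)
  }
  if (min_tracks < length(use)) {
    combos <- utils::combn(seq_along(use), min_tracks, simplify = FALSE)
    inter_list <- lapply(combos, function(ix) n_way_intersect(use[ix]))
    lens <- vapply(inter_list, function(x) {
      if (nrow(x)) max(x$end - x$start) else 0
    }, numeric(1))
    inter <- inter_list[[which.max(lens)]]
  } else {
    inter <- n_way_intersect(use)
  }
  if (nrow(inter) == 0) return(no_call(spans, "empty evidence intersection"))
  raw <- inter[which.max(inter$end - inter$start), , drop = FALSE]

  snapped <- raw
  snap_ids <- character(0)
  if (!is.null(contigs)) {
    ci <- contigs[contigs$chrom == raw$chrom, , drop = FALSE]
    if (nrow(ci)) {
      left <- contig_at(ci, raw$chrom, raw$start)
      if (is.na(left)) left <- which(ci$start >= raw$start)[1]  # nearest inner
      right <- contig_at(ci, raw$chrom, raw$end - 1)
      if (is.na(right)) right <- utils::tail(which(ci$end <= raw$end), 1)
      if (length(left) && length(right) && !is.na(left) && !is.na(right) &&
          left <= right) {
        snapped$start <- ci$start[left]
        snapped$end <- ci$end[right]
        snap_ids <- ci$contig_id[c(left, right)]
      }
    }
  }
  structure(list(called = TRUE, chrom = raw$chrom,
                 raw_interval = as_interval_set(raw),
                 snapped_interval = as_interval_set(snapped),
                 length_bp = snapped$end - snapped$start,
                 track_intervals = spans, snap_contigs = snap_ids,
                 diagnostics = NULL),
            class = "sdr_call")
}

no_call <- function(spans, reason) {
  structure(list(called = FALSE, chrom = NA_character_,
                 raw_interval = interval_set(),
                 snapped_interval = interval_set(), length_bp = 0,
                 track_intervals = spans, snap_contigs = character(0),
                 diagnostics = reason),
            class = "sdr_call")
}

#' @export
print.sdr_call <- function(x, ...) {
  if (!x$called) {
    cat("<sdr_call> no call:", x$diagnostics, "\n")
  } else {
    cat(sprintf("<sdr_call> %s:%.2f-%.2f Mb (%.2f Mb; raw %.2f-%.2f Mb)\n",
                x$chrom, x$snapped_interval$start / 1e6,
                x$snapped_interval$end / 1e6, x$length_bp / 1e6,
                x$raw_interval$start / 1e6, x$raw_interval$end / 1e6))
  }
  invisible(x)
}

#' Full SDR scan
#'
#' Builds all available evidence tracks and delimits the SDR.
#'
#' @inheritParams build_evidence_tracks
#' @param min_tracks see [delimit_sdr()].
#' @return A list `tracks`, `call`.
#' @export
sdr_scan <- function(sites, sheet, chrom_lengths, cfg = dioscan_config(),
                     f1_sites = NULL, f1_sheet = NULL, contigs = NULL,
                     min_tracks = NULL) {
  if (is.null(min_tracks)) min_tracks <- cfg$min_tracks
  tracks <- build_evidence_tracks(sites, sheet, chrom_lengths, cfg,
                                  f1_sites = f1_sites, f1_sheet = f1_sheet,
                                  contigs = contigs)
  call <- delimit_sdr(tracks, contigs = contigs, min_tracks = min_tracks)
  list(tracks = tracks, call = call)
}
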