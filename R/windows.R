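#' Sliding and tiling genome windows
#'
#' Builds the windows underlying every scan. Windows start at 0 and advance by
#' `step`; a window running past the chromosome end is truncated and kept only
#' if it still covers at least `step` bases, so terminal stubs shorter than
#' the step are dropped. `covered_length` records the truncated extent and is
#' the denominator for per-bp densities.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param size window size in bp.
#' @param step step in bp (`size >= step >= 1`; `step == size` tiles).
#' @return A data frame with `chrom`, `start`, `end` (0-based half-open),
#'   `covered_length`, and attributes `size`/`step`.
#' @examples
#' make_windows(c(chr1 = 120), size = 100, step = 50)
#' @export
make_windows <- function(chrom_lengths, size, step = size) {
  stopifnot(is.numeric(chrom_lengths), length(chrom_lengths) >= 1,
            !is.null(names(chrom_lengths)))
  if (!is.numeric(size) || size <= 0 || !is.numeric(step) || step <= 0) {
    stop("make_windows: size and step must be positive")
  }
  if (step > size) stop("make_windows: step must not exceed size")
  res <- lapply(names(chrom_lengths), function(chr) {
    len <- chrom_lengths[[chr]]
    starts <- seq(0, max(0, len - 1), by = step)
    ends <- pmin(starts + size, len)
    keep <- (ends - starts) >= step
    data.frame(chrom = rep(chr, sum(keep)), start = starts[keep],
               end = ends[keep], covered_length = (ends - starts)[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "size") <- size
  attr(out, "step") <- step
  out
}

#' Upper-tail nearest-rank quantile cutoff
#'
#' Returns the cutoff value such that windows with `value >= cutoff` form the
#' top `q` fraction under the nearest-rank convention: the cutoff is the
#' `floor((1 - q) * n) + 1`-th smallest non-missing value (capped at the
#' maximum). For `n = 100` and `q = 0.01` this selects the single maximum,
#' matching "top 1%" usage on 100-rank tracks.
#'
#' @param values numeric vector of per-window statistic values (NAs are
#'   ignored; `Inf` ranks above all finite values).
#' @param q upper-tail fraction, `0 < q < 1`.
#' @return The cutoff value.
#' @examples
#' threshold_by_quantile(1:100, 0.01)  # 100
#' threshold_by_quantile(1:100, 0.05)  # 96
#' @export
threshold_by_quantile <- function(values, q) {
  stopifnot(is.numeric(q), length(q) == 1, q > 0, q < 1)
  v <- values[!is.na(values)]
  if (length(v) == 0) stop("threshold_by_quantile: all values are missing (empty track)")
  v <- sort(v)
  rank <- min(floor((1 - q) * length(v)) + 1, length(v))
  v[rank]
}

## internal: indices of sites (sorted 0-based positions pos0) per window.
## Returns per-window [i1, i2] such that sites i1..i2 fall in [start, end);
## i2 < i1 means empty. Windows and positions must be from one chromosome.
window_site_range <- function(pos0, starts, ends) {
  i1 <- findInterval(starts - 0.5, pos0) + 1
  i2 <- findInterval(ends - 0.5, pos0)
  list(i1 = i1, i2 = i2)
}

## internal: per-window sums of per-site values via cumsum, by chromosome.
## sites: data.frame(chrom, pos0) sorted by (chrom, pos0); x: matrix or vector
## of per-site values (rows = sites). Returns matrix n_windows x ncol(x).
window_sums <- function(site_chrom, site_pos0, x, windows) {
  x <- as.matrix(x)
  out <- matrix(0, nrow = nrow(windows), ncol = ncol(x))
  nsites <- integer(nrow(windows))
  for (chr in unique(windows$chrom)) {
    wi <- which(windows$chrom == chr)
    si <- which(site_chrom == chr)
    if (length(si) == 0) next
    pos0 <- site_pos0[si]
    rng <- window_site_range(pos0, windows$start[wi], windows$end[wi])
    xs <- x[si, , drop = FALSE]
    xs[is.na(xs)] <- 0
    cs <- apply(xs, 2, cumsum)
    cs <- rbind(0, cs)
    out[wi, ] <- cs[rng$i2 + 1, , drop = FALSE] - cs[rng$i1, , drop = FALSE]
    nsites[wi] <- pmax(rng$i2 - rng$i1 + 1, 0)
  }
  attr(out, "n_sites") <- nsites
  out
}

#' Windowed feature density
#'
#' Counts point features (positions) or interval features (e.g. contigs) per
#' window. Point features are counted in every window containing them;
#' interval features are counted once in every window they overlap. Densities
#' are either raw counts (`normalize = FALSE`, used for co-segregation contig
#' counts) or counts per covered base (`normalize = TRUE`, used for SNP
#' densities).
#'
#' @param features for points: a data frame with `chrom` and 1-based `pos`;
#'   for intervals: a data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param windows a window table from [make_windows()].
#' @param normalize divide counts by `covered_length`?
#' @return `windows` with columns `count` and `value` (the density) appended.
#' @export
windowed_density <- function(features, windows, normalize = TRUE) {
  n <- nrow(windows)
  count <- numeric(n)
  if (!is.null(features$pos)) {
    ord <- order(features$chrom, features$pos)
    chrom <- features$chrom[ord]
    pos0 <- features$pos[ord] - 1
    if (length(pos0) > 0) {
      cnt <- window_sums(chrom, pos0, rep(1, length(pos0)), windows)
      count <- cnt[, 1]
    }
  } else {
    fgr <- iv_to_gr(features$chrom, features$start, features$end)
    wgr <- iv_to_gr(windows$chrom, windows$start, windows$end)
    count <- GenomicRanges::countOverlaps(wgr, fgr)
  }
  windows$count <- count
  windows$value <- if (normalize) count / windows$covered_length else count
  windows
}
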