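#' Interval sets
#'
#' An `interval_set` is an ordered, non-overlapping collection of genomic
#' intervals in 0-based half-open coordinates, the convention used internally
#' throughout dioscan (VCF positions are converted on input, BED output is
#' native). The constructor normalizes its input: intervals are sorted by
#' chromosome and start, and overlapping or touching intervals are unioned.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors, 0-based half-open (`start < end`).
#' @return A data frame with columns `chrom`, `start`, `end` and class
#'   `interval_set`.
#' @examples
#' interval_set("chr1", c(0, 50), c(60, 100))  # touching -> one interval
#' @export
interval_set <- function(chrom = character(), start = numeric(), end = numeric()) {
  stopifnot(length(start) == length(end))
  chrom <- rep_len(as.character(chrom), length(start))
  if (length(start) > 0) {
    if (any(is.na(chrom) | is.na(start) | is.na(end))) {
      stop("interval_set: NA coordinates are not allowed")
    }
    if (any(end <= start)) stop("interval_set: intervals must satisfy start < end")
    if (any(start < 0)) stop("interval_set: negative start coordinate")
  }
  gr <- GenomicRanges::reduce(iv_to_gr(chrom, start, end))
  gr_to_iv(gr)
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set> %d interval(s), %s bp total\n",
              nrow(x), format(sum(x$end - x$start), big.mark = ",")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

## internal: 0-based half-open <-> GRanges (1-based closed)
iv_to_gr <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1, end = end))
}

gr_to_iv <- function(gr) {
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interval_set", "data.frame")
  out
}

as_interval_set <- function(x) {
  if (inherits(x, "interval_set")) return(x)
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  interval_set(x$chrom, x$start, x$end)
}

#' Merge intervals within a gap
#'
#' Unions intervals whose gap is at most `max_gap` base pairs (inclusive, so
#' the field's "merged if within 4 kb" rule is `max_gap = 4000`). Overlapping
#' and touching intervals always merge.
#'
#' @param intervals an [interval_set()] or coercible data frame.
#' @param max_gap non-negative integer gap in bp; intervals separated by at
#'   most this many bases are unioned.
#' @return An [interval_set()].
#' @examples
#' merge_intervals(interval_set("chr1", c(0, 5000), c(1000, 6000)), max_gap = 4000)
#' @export
merge_intervals <- function(intervals, max_gap = 0) {
  stopifnot(is.numeric(max_gap), length(max_gap) == 1, max_gap >= 0)
  x <- as_interval_set(intervals)
  if (nrow(x) == 0) return(x)
  gr <- GenomicRanges::reduce(iv_to_gr(x$chrom, x$start, x$end),
                              min.gapwidth = max_gap + 1)
  gr_to_iv(gr)
}

#' Intersect two or more interval sets
#'
#' Exact n-way intersection: a base is in the result iff it is covered by
#' every input set. Used to combine independent evidence tracks into a single
#' candidate region.
#'
#' @param sets a list of two or more [interval_set()]s (or coercible data
#'   frames).
#' @return An [interval_set()] (possibly empty).
#' @examples
#' a <- interval_set("chr1", 141.1e6, 165.7e6)
#' b <- interval_set("chr1", 145.0e6, 162.7e6)
#' intersect_interval_sets(list(a, b))
#' @export
intersect_interval_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2)
  grs <- lapply(sets, function(s) {
    s <- as_interval_set(s)
    iv_to_gr(s$chrom, s$start, s$end)
  })
  out <- Reduce(function(a, b) {
    suppressWarnings(GenomicRanges::intersect(a, b, ignore.strand = TRUE))
  }, grs)
  gr_to_iv(out)
}

#' Total length of an interval set
#' @param intervals an [interval_set()].
#' @return Total covered bases.
#' @export
interval_length <- function(intervals) {
  x <- as_interval_set(intervals)
  sum(x$end - x$start)
}

#' Jaccard index between two interval sets
#'
#' Length of the intersection over length of the union; the recovery metric
#' used to compare called regions against simulated truth regions.
#'
#' @param a,b interval sets.
#' @return A number in \[0, 1\] (1 when both sets are empty).
#' @export
interval_jaccard <- function(a, b) {
  a <- as_interval_set(a); b <- as_interval_set(b)
  if (nrow(a) == 0 && nrow(b) == 0) return(1)
  inter <- interval_length(intersect_interval_sets(list(a, b)))
  uni <- interval_length(interval_set(c(a$chrom, b$chrom),
                                      c(a$start, b$start),
                                      c(a$end, b$end)))
  if (uni == 0) return(1)
  inter / uni
}

#' Write intervals as BED
#'
#' BED is 0-based half-open, matching the internal convention, so coordinates
#' are written unchanged.
#'
#' @param intervals an [interval_set()] or data frame with `chrom`, `start`,
#'   `end` (extra columns `name`, `score`, `strand` are honored).
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  x <- as.data.frame(intervals)
  n <- nrow(x)
  bed <- data.frame(
    chrom = x$chrom,
    start = format(x$start, scientific = FALSE, trim = TRUE),
    end = format(x$end, scientific = FALSE, trim = TRUE),
    name = if ("name" %in% names(x)) x$name else rep(".", n),
    score = if ("score" %in% names(x)) x$score else rep(0, n),
    strand = if ("strand" %in% names(x)) x$strand else rep(".", n),
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file as intervals
#' @param path BED file (first three columns used; a `name` column is kept
#'   when present).
#' @return A data frame with `chrom`, `start`, `end` (+ `name`), 0-based
#'   half-open. Not normalized: rows are returned as stored.
#' @export
read_bed <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(x[[1]]), start = as.numeric(x[[2]]),
                    end = as.numeric(x[[3]]), stringsAsFactors = FALSE)
  if (ncol(x) >= 4) out$name <- as.character(x[[4]])
  out
}
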