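#' Contig maps
#'
#' A contig map records the placement of assembly contigs on chromosomes and
#' is used to snap called region boundaries to contig terminals. Coordinates
#' are 0-based half-open; contigs on one chromosome must not overlap.
#'
#' @param contig_id,chrom character vectors.
#' @param start,end numeric, 0-based half-open placements.
#' @param orientation `"+"` or `"-"` per contig.
#' @return A data frame of class `contig_map`, sorted by chromosome and start.
#' @export
contig_map <- function(contig_id, chrom, start, end, orientation = "+") {
  x <- data.frame(contig_id = as.character(contig_id),
                  chrom = as.character(chrom),
                  start = as.numeric(start), end = as.numeric(end),
                  orientation = rep_len(orientation, length(contig_id)),
                  stringsAsFactors = FALSE)
  if (any(x$end <= x$start)) stop("contig_map: start < end required")
  if (!all(x$orientation %in% c("+", "-"))) {
    stop("contig_map: orientation must be '+' or '-'")
  }
  x <- x[order(x$chrom, x$start), ]
  for (chr in unique(x$chrom)) {
    xi <- x[x$chrom == chr, ]
    if (nrow(xi) > 1 && any(xi$start[-1] < xi$end[-nrow(xi)])) {
      stop("contig_map: overlapping contigs on ", chr)
    }
  }
  rownames(x) <- NULL
  class(x) <- c("contig_map", "data.frame")
  x
}

#' Read a contig map (AGP v2.1 or 5-column TSV)
#'
#' AGP files (tab-separated, 9 columns, `W`/`F` component lines) are detected
#' by their column signature; otherwise the file is read as a headered TSV
#' with columns `contig_id`, `chrom`, `start`, `end`, `orientation`
#' (0-based half-open).
#'
#' @param path input file.
#' @return A [contig_map()].
#' @export
read_contig_map <- function(path) {
  first <- readLines(path, n = 50)
  first <- first[!startsWith(first, "#")]
  nfields <- length(strsplit(first[1], "\t", fixed = TRUE)[[1]])
  if (nfields == 9) {
    x <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
    comp <- x[x[[5]] %in% c("W", "F", "O", "A", "D"), ]
    contig_map(contig_id = comp[[6]], chrom = comp[[1]],
               start = as.numeric(comp[[2]]) - 1, end = as.numeric(comp[[3]]),
               orientation = ifelse(comp[[9]] == "-", "-", "+"))
  } else {
    x <- utils::read.delim(path, stringsAsFactors = FALSE)
    contig_map(x$contig_id, x$chrom, x$start, x$end, x$orientation)
  }
}

#' Write a contig map TSV
#' @param contigs a [contig_map()].
#' @param path output path.
#' @export
write_contig_map <- function(contigs, path) {
  utils::write.table(as.data.frame(contigs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## internal: contig index containing each (chrom, pos0) or NA
contig_at <- function(contigs, chrom, pos0) {
  idx <- rep(NA_integer_, length(pos0))
  for (chr in unique(chrom)) {
    ci <- which(contigs$chrom == chr)
    pi <- which(chrom == chr)
    if (!length(ci)) next
    hit <- findInterval(pos0[pi], contigs$start[ci])
    ok <- hit >= 1 & hit <= length(ci)
    ok[ok] <- pos0[pi][ok] < contigs$end[ci][hit[ok]]
    idx[pi[ok]] <- ci[hit[ok]]
  }
  idx
}
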