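#' Write and read windowed statistic tracks
#'
#' Tracks are TSVs with columns `chrom`, `start`, `end` (0-based half-open),
#' `value`, and `pass` (logical flag for windows at or above the track
#' cutoff). Round-trips exactly through [read_track()].
#'
#' @param track a data frame with at least `chrom`, `start`, `end`, `value`;
#'   `pass` is written as 0/1 (absent -> 0).
#' @param path output path.
#' @export
write_track <- function(track, path) {
  out <- data.frame(chrom = track$chrom,
                    start = format(track$start, scientific = FALSE, trim = TRUE),
                    end = format(track$end, scientific = FALSE, trim = TRUE),
                    value = ifelse(is.na(track$value), "NA",
                                   formatC(track$value, format = "g",
                                           digits = 17, width = 1)),
                    pass = as.integer(isTRUE_vec(track$pass, nrow(track))),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

isTRUE_vec <- function(x, n) {
  if (is.null(x)) return(rep(FALSE, n))
  !is.na(x) & x
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  x$value <- as.numeric(x$value)
  x$pass <- as.logical(x$pass)
  x
}
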