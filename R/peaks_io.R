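#' Read a BED or narrowPeak file of peak calls
#'
#' Parses tab-separated interval files in the BED3+ or ENCODE narrowPeak
#' dialects. Coordinates are 0-based half-open, as in the BED standard.
#' Lines starting with \code{track}, \code{browser} or \code{#} are skipped.
#' For narrowPeak input the statistical columns (score, signalValue, pValue,
#' qValue, peak) are ignored: only the interval matters for binarization.
#'
#' @param path Path to the file.
#' @param format Either \code{"bed"} or \code{"narrowPeak"}. Both are parsed
#'   identically from their first three columns; the argument documents intent
#'   and (for narrowPeak) requires at least 10 columns.
#' @return A \code{\link[GenomicRanges]{GRanges}} of the intervals. Note that
#'   GRanges uses 1-based closed coordinates internally; a BED line
#'   \code{chr1 250 450} becomes \code{chr1:251-450}. Intervals on
#'   chromosomes absent from any downstream grid are retained here and only
#'   dropped at binning time.
#' @seealso \code{\link{bin_and_binarize}}
#' @export
read_peak_file <- function(path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_granges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  min_cols <- if (format == "narrowPeak") 10L else 3L
  if (any(nf < min_cols))
    stop(sprintf("line %d: expected at least %d tab-separated fields, got %d",
                 line_no[which(nf < min_cols)[1L]], min_cols,
                 nf[which(nf < min_cols)[1L]]))
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad))
    stop(sprintf("line %d: non-integer coordinates", line_no[bad[1L]]))
  bad <- which(start >= end | start < 0)
  if (length(bad))
    stop(sprintf("line %d: invalid interval (start %s, end %s)",
                 line_no[bad[1L]], start[bad[1L]], end[bad[1L]]))
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end))
}

empty_granges <- function() {
  GenomicRanges::GRanges()
}

#' Write intervals as a BED3 file
#'
#' @param gr A GRanges (1-based closed, as returned by
#'   \code{\link{read_peak_file}}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
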