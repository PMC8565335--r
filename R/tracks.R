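#' Binary track over a bin grid
#'
#' One (cell type, assay) pair represented as a 0/1 vector over all bins of a
#' \code{\link{bin_grid}}.
#'
#' @param cell Cell-type identifier.
#' @param assay Assay identifier (e.g. \code{"accessibility"} or a ChIP-seq
#'   target name).
#' @param values Integer vector in \{0, 1\}, length \code{grid$total_bins}.
#' @param grid A \code{bin_grid}.
#' @return An object of class \code{binned_track}.
#' @export
binned_track <- function(cell, assay, values, grid) {
  values <- as.integer(values)
  if (length(values) != grid$total_bins)
    stop("values length does not match grid bin count")
  if (!all(values %in% c(0L, 1L))) stop("track values must be 0/1")
  structure(list(cell = cell, assay = assay, values = values, grid = grid),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("binned_track %s | %s: %d / %d bins positive\n",
              x$cell, x$assay, sum(x$values), length(x$values)))
  invisible(x)
}

#' Bin and binarize peak intervals
#'
#' Marks a bin positive iff at least one interval overlaps it by at least
#' 1 bp. Intervals on chromosomes absent from the grid are dropped with a
#' warning.
#'
#' @param intervals A GRanges of peaks (as from \code{\link{read_peak_file}}).
#' @param grid A \code{\link{bin_grid}}.
#' @param cell,assay Identifiers stored on the returned track.
#' @return A \code{\link{binned_track}}.
#' @examples
#' g <- bin_grid(c(chr1 = 2000))
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(251, 450)) # BED 250-450
#' which(bin_and_binarize(gr, g)$values == 1)  # bins 2 and 3 (1-based)
#' @export
bin_and_binarize <- function(intervals, grid, cell = "cell", assay = "assay") {
  values <- integer(grid$total_bins)
  if (length(intervals) > 0L) {
    chrom <- as.character(GenomicRanges::seqnames(intervals))
    known <- chrom %in% names(grid$chrom_lengths)
    if (!all(known)) {
      warning("dropping ", sum(!known),
              " interval(s) on chromosomes absent from the grid: ",
              paste(unique(chrom[!known]), collapse = ", "))
      intervals <- intervals[known]
      chrom <- chrom[known]
    }
    if (length(intervals) > 0L) {
      # back to 0-based half-open for the bin arithmetic
      start0 <- GenomicRanges::start(intervals) - 1L
      end0 <- GenomicRanges::end(intervals)
      first_bin <- start0 %/% grid$bin_size
      last_bin <- (end0 - 1L) %/% grid$bin_size
      # clip to the chromosome's bin range
      last_bin <- pmin(last_bin, unname(grid$n_bins[chrom]) - 1L)
      first_bin <- pmax(first_bin, 0L)
      ok <- first_bin <= last_bin
      if (any(ok)) {
        n_hit <- last_bin[ok] - first_bin[ok] + 1L
        gbins <- sequence(n_hit) - 1L +
          rep(global_bin(grid, chrom[ok], first_bin[ok]), n_hit)
        values[unique(gbins)] <- 1L
      }
    }
  }
  binned_track(cell, assay, values, grid)
}

#' Merge replicate tracks by consensus
#'
#' Replicate peak sets for one (cell type, assay) pair are merged as:
#' 1 replicate is returned unchanged; with 2 replicates all peaks are kept
#' (union); with 3 replicates, bins positive in at least two; with 4 or more
#' replicates, bins positive in at least 25\% of replicates (threshold
#' \code{ceiling(0.25 * n)}).
#'
#' @param replicate_tracks List of \code{\link{binned_track}} on the same grid.
#' @return A single merged \code{binned_track} (cell/assay taken from the
#'   first replicate).
#' @export
consensus_merge <- function(replicate_tracks) {
  if (length(replicate_tracks) < 1L) stop("need at least one replicate")
  grids <- lapply(replicate_tracks, `[[`, "grid")
  if (!all(vapply(grids[-1], identical, logical(1), y = grids[[1]])))
    stop("replicate tracks are on different grids")
  n <- length(replicate_tracks)
  if (n == 1L) return(replicate_tracks[[1L]])
  counts <- Reduce(`+`, lapply(replicate_tracks, `[[`, "values"))
  threshold <- switch(as.character(min(n, 4L)),
                      "2" = 1L, "3" = 2L, "4" = as.integer(ceiling(0.25 * n)))
  binned_track(replicate_tracks[[1L]]$cell, replicate_tracks[[1L]]$assay,
               as.integer(counts >= threshold), replicate_tracks[[1L]]$grid)
}

#' Export a track's positive bins as intervals
#'
#' @param track A \code{\link{binned_track}}.
#' @return A GRanges with one range per positive bin (not merged, so that the
#'   BED round trip through \code{\link{bin_and_binarize}} is exact).
#' @export
track_to_granges <- function(track) {
  pos <- which(track$values == 1L)
  if (length(pos) == 0L) return(empty_granges())
  co <- bin_coords(track$grid, pos)
  GenomicRanges::GRanges(co$chrom, IRanges::IRanges(co$start + 1L, co$end))
}

#' Write a track's positive bins to a BED3 file
#'
#' @param track A \code{\link{binned_track}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_track_bed <- function(track, path) {
  write_bed(track_to_granges(track), path)
}
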