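#' Genome bin grid
#'
#' Partitions a genome into fixed-width bins. Bin \code{i} (0-based, per
#' chromosome) covers the 0-based half-open interval
#' \code{[i * bin_size, (i + 1) * bin_size)}. Chromosomes are laid out in the
#' order given, and bins are addressed package-wide by a global 1-based index
#' running over chromosomes in that order.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param bin_size Bin width in bp (default 200).
#' @return An object of class \code{bin_grid} with elements
#'   \code{bin_size}, \code{chrom_lengths}, \code{n_bins} (bins per
#'   chromosome), \code{offsets} (global index of the bin before each
#'   chromosome's first bin) and \code{total_bins}.
#' @examples
#' g <- bin_grid(c(chr1 = 1000, chr2 = 450))
#' g$total_bins  # 5 + 3
#' @export
bin_grid <- function(chrom_lengths, bin_size = 200L) {
  stopifnot(bin_size > 0)
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == ""))
    stop("chrom_lengths must be a named vector")
  if (anyDuplicated(names(chrom_lengths)))
    stop("duplicated chromosome names in chrom_lengths")
  if (any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive")
  n_bins <- as.integer(ceiling(chrom_lengths / bin_size))
  names(n_bins) <- names(chrom_lengths)
  offsets <- c(0L, cumsum(n_bins))[seq_along(n_bins)]
  names(offsets) <- names(chrom_lengths)
  structure(
    list(bin_size = as.integer(bin_size),
         chrom_lengths = chrom_lengths,
         n_bins = n_bins,
         offsets = offsets,
         total_bins = sum(n_bins)),
    class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("bin_grid: %d chromosomes, %d bp bins, %d bins total\n",
              length(x$chrom_lengths), x$bin_size, x$total_bins))
  invisible(x)
}

#' Read a chromosome sizes file
#'
#' Reads the two-column tab-separated "chrom sizes" dialect
#' (chromosome name, length in bp) and returns a \code{\link{bin_grid}}.
#'
#' @param path Path to the TSV file.
#' @param bin_size Bin width in bp (default 200).
#' @return A \code{bin_grid}.
#' @export
read_chrom_sizes <- function(path, bin_size = 200L) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  lens <- tab$length
  names(lens) <- tab$chrom
  bin_grid(lens, bin_size = bin_size)
}

#' Map chromosome-local bins to global bin indices
#'
#' @param grid A \code{bin_grid}.
#' @param chrom Chromosome name (scalar or vector, recycled).
#' @param bin 0-based bin index within the chromosome.
#' @return Global 1-based bin indices.
#' @export
global_bin <- function(grid, chrom, bin) {
  off <- grid$offsets[chrom]
  if (anyNA(off)) stop("unknown chromosome: ",
                       paste(unique(chrom[is.na(off)]), collapse = ", "))
  unname(off + bin + 1L)
}

#' Describe global bin indices
#'
#' @param grid A \code{bin_grid}.
#' @param bins Global 1-based bin indices.
#' @return data.frame with columns chrom, start, end (0-based half-open bp
#'   coordinates; the last bin of a chromosome is clipped to its length).
#' @export
bin_coords <- function(grid, bins) {
  if (any(bins < 1L | bins > grid$total_bins)) stop("bin index off the grid")
  chrom_idx <- findInterval(bins - 1L, unname(grid$offsets))
  chrom <- names(grid$n_bins)[chrom_idx]
  local <- bins - 1L - unname(grid$offsets)[chrom_idx]
  start <- local * grid$bin_size
  end <- pmin(start + grid$bin_size, unname(grid$chrom_lengths[chrom_idx]))
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Chromosome of each global bin
#' @param grid A \code{bin_grid}.
#' @return Character vector of length \code{grid$total_bins}.
#' @keywords internal
bin_chroms <- function(grid) {
  rep(names(grid$n_bins), grid$n_bins)
}
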