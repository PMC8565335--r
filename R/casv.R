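#' CASV window configuration
#'
#' The chromatin accessibility similarity vector (CASV) compares two binary
#' accessibility tracks around a bin over nested, centered windows; each
#' window is reduced to its exclusive ring (the bins not covered by the next
#' smaller window) so the resolutions do not overlap. Window sizes are odd
#' bin counts; the defaults (1, 5, 19, 59) span up to about 12 kb of context
#' at 200 bp bins, with exclusive ring sizes 1, 4, 14 and 40.
#'
#' @param ring_bins Strictly increasing odd window sizes in bins; the first
#'   must be 1.
#' @return Object of class \code{casv_windows} with elements \code{sizes},
#'   \code{half} (half-widths) and \code{ring_sizes}.
#' @export
casv_windows <- function(ring_bins = c(1L, 5L, 19L, 59L)) {
  ring_bins <- as.integer(ring_bins)
  if (length(ring_bins) < 1L || ring_bins[1L] != 1L)
    stop("first window size must be 1")
  if (any(diff(ring_bins) <= 0L)) stop("window sizes must strictly increase")
  if (any(ring_bins %% 2L == 0L)) stop("window sizes must be odd (centered)")
  structure(list(sizes = ring_bins,
                 half = (ring_bins - 1L) %/% 2L,
                 ring_sizes = diff(c(0L, ring_bins))),
            class = "casv_windows")
}

# Window sums around each bin for many bins at once.
#
# For every global bin index and every window size, computes the sum of `x`
# (a per-bin vector over the whole grid) in the centered window, treating
# bins beyond the chromosome boundary as having value `pad` (0 for peak
# products, 1 for agreement indicators). Returns an n x m matrix.
window_sums <- function(bins, x, grid, windows, pad) {
  chrom_idx <- findInterval(bins - 1L, unname(grid$offsets))
  L <- unname(grid$n_bins)[chrom_idx]
  off <- unname(grid$offsets)[chrom_idx]
  i_local <- bins - off
  out <- matrix(0, length(bins), length(windows$sizes))
  # per-chromosome cumulative sums; grid chromosomes visited lazily
  cs_cache <- vector("list", length(grid$n_bins))
  for (ci in unique(chrom_idx)) {
    if (is.null(cs_cache[[ci]])) {
      rng <- (grid$offsets[ci] + 1L):(grid$offsets[ci] + grid$n_bins[ci])
      cs_cache[[ci]] <- c(0, cumsum(x[rng]))
    }
  }
  for (z in seq_along(windows$sizes)) {
    h <- windows$half[z]
    lo <- pmax(1L, i_local - h)
    hi <- pmin(L, i_local + h)
    inside <- numeric(length(bins))
    for (ci in unique(chrom_idx)) {
      sel <- chrom_idx == ci
      cs <- cs_cache[[ci]]
      inside[sel] <- cs[hi[sel] + 1L] - cs[lo[sel]]
    }
    n_outside <- (h - (i_local - lo)) + (h - (hi - i_local))
    out[, z] <- inside + pad * n_outside
  }
  out
}

# Full CASV blocks for many bins at once: returns n x (2m) matrix,
# positive part (columns 1..m) then agreement part (columns m+1..2m).
casv_block <- function(bins, q_values, k_values, grid,
                       windows = casv_windows()) {
  if (length(q_values) != grid$total_bins ||
      length(k_values) != grid$total_bins)
    stop("track length does not match grid")
  eq <- as.numeric(q_values == k_values)
  pp <- as.numeric(q_values * k_values)
  w_pos <- window_sums(bins, pp, grid, windows, pad = 0)
  w_agr <- window_sums(bins, eq, grid, windows, pad = 1)
  m <- length(windows$sizes)
  ring <- function(w) {
    r <- w
    if (m > 1L) r[, 2:m] <- w[, 2:m, drop = FALSE] - w[, 1:(m - 1), drop = FALSE]
    sweep(r, 2L, windows$ring_sizes, "/")
  }
  cbind(ring(w_pos), ring(w_agr))
}

check_casv_args <- function(i, a_q, a_k) {
  stopifnot(inherits(a_q, "binned_track"), inherits(a_k, "binned_track"))
  if (!identical(a_q$grid, a_k$grid)) stop("tracks are on different grids")
  if (any(i < 1L | i > a_q$grid$total_bins)) stop("bin index off the grid")
}

#' Agreement part of the CASV
#'
#' For each exclusive ring around bin \code{i}, the fraction of ring bins on
#' which the two tracks agree (both peak or both non-peak). Bins beyond the
#' chromosome boundary are treated as non-peak in both tracks and therefore
#' count as agreement; denominators stay at the full ring size.
#'
#' @param i Global bin index (may be a vector).
#' @param a_q,a_k Query and reference \code{\link{binned_track}} on the same
#'   grid.
#' @param windows A \code{\link{casv_windows}}.
#' @return Numeric vector of ring fractions (or a matrix with one row per
#'   \code{i}).
#' @export
agreement_casv <- function(i, a_q, a_k, windows = casv_windows()) {
  check_casv_args(i, a_q, a_k)
  m <- length(windows$sizes)
  b <- casv_block(i, a_q$values, a_k$values, a_q$grid, windows)[, (m + 1):(2 * m),
                                                               drop = FALSE]
  if (length(i) == 1L) drop(b) else b
}

#' Shared-peak part of the CASV
#'
#' For each exclusive ring around bin \code{i}, the fraction of ring bins in
#' which both tracks carry a peak. Boundary bins contribute 0.
#'
#' @inheritParams agreement_casv
#' @return Numeric vector of ring fractions (or a matrix with one row per
#'   \code{i}).
#' @export
positive_casv <- function(i, a_q, a_k, windows = casv_windows()) {
  check_casv_args(i, a_q, a_k)
  m <- length(windows$sizes)
  b <- casv_block(i, a_q$values, a_k$values, a_q$grid, windows)[, 1:m,
                                                               drop = FALSE]
  if (length(i) == 1L) drop(b) else b
}

#' Chromatin accessibility similarity vector
#'
#' Concatenation of the shared-peak fractions and the agreement fractions
#' over the exclusive rings: with default windows the result has length 8.
#' The CASV is symmetric in its two track arguments.
#'
#' @inheritParams agreement_casv
#' @return Numeric vector of length \code{2 * length(windows$sizes)} (or a
#'   matrix with one row per \code{i}).
#' @examples
#' g <- bin_grid(c(chr1 = 40000))
#' a <- binned_track("q", "accessibility", integer(200), g)
#' casv(100, a, a)  # (0,0,0,0, 1,1,1,1): empty tracks agree everywhere
#' @export
casv <- function(i, a_q, a_k, windows = casv_windows()) {
  check_casv_args(i, a_q, a_k)
  b <- casv_block(i, a_q$values, a_k$values, a_q$grid, windows)
  if (length(i) == 1L) drop(b) else b
}

#' Multi-assay CASV
#'
#' Extends the CASV to additional assays (typically histone-mark ChIP-seq
#' measured in both the query context and the reference cell types): the CASV
#' is computed per assay and the blocks concatenated in \code{assay_order},
#' giving a vector of length \code{8 * m} for m assays with default windows.
#'
#' @param i Global bin index (scalar or vector).
#' @param query_tracks,ref_tracks Named lists mapping assay name to
#'   \code{\link{binned_track}} for the query and the reference cell type.
#' @param assay_order Character vector fixing the block order (accessibility
#'   first by convention); every listed assay must be present on both sides.
#' @param windows A \code{\link{casv_windows}}.
#' @return Numeric vector (or matrix with one row per \code{i}).
#' @export
multi_assay_casv <- function(i, query_tracks, ref_tracks, assay_order,
                             windows = casv_windows()) {
  missing_q <- setdiff(assay_order, names(query_tracks))
  missing_k <- setdiff(assay_order, names(ref_tracks))
  if (length(missing_q) || length(missing_k))
    stop("assay(s) missing from ",
         if (length(missing_q)) "query" else "reference", " tracks: ",
         paste(unique(c(missing_q, missing_k)), collapse = ", "))
  blocks <- lapply(assay_order, function(a) {
    check_casv_args(i, query_tracks[[a]], ref_tracks[[a]])
    casv_block(i, query_tracks[[a]]$values, ref_tracks[[a]]$values,
               query_tracks[[a]]$grid, windows)
  })
  b <- do.call(cbind, blocks)
  if (length(i) == 1L) drop(b) else b
}

#' Identity (constant) CASV
#'
#' The similarity vector of an empty track against itself: shared-peak part
#' all zero, agreement part all one. Used as a constant stand-in for the CASV
#' in the ablation where no accessibility information enters the model, so
#' all reference cell types look equally similar everywhere.
#'
#' @param windows A \code{\link{casv_windows}}.
#' @param n_assays Number of assay blocks (default 1).
#' @return Numeric vector of length \code{2 * length(windows$sizes) * n_assays}.
#' @export
identity_casv <- function(windows = casv_windows(), n_assays = 1L) {
  m <- length(windows$sizes)
  rep(c(rep(0, m), rep(1, m)), n_assays)
}
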