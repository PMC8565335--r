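#' Fraction of peaks unique to a held-out cell type
#'
#' Given the peak set \code{A} of a held-out cell type and a pooled reference
#' peak set \code{B}, returns \code{|A \\ B| / |A|}: the fraction of the
#' held-out cell's peaks that no reference cell carries. This bounds the
#' sensitivity achievable by any method that can only predict events already
#' observed in a reference cell type.
#'
#' @param a Peak set of the held-out cell type (vector of bin indices; must be
#'   nonempty).
#' @param b Pooled reference peak set (vector of bin indices, possibly empty).
#' @return Fraction in \[0, 1\].
#' @export
fraction_unique_peaks <- function(a, b) {
  a <- unique(a)
  if (length(a) == 0L) stop("held-out peak set A is empty")
  length(setdiff(a, b)) / length(a)
}

#' Unique-peak fraction as a function of reference pool size
#'
#' Monte Carlo estimate of how the fraction of peaks unique to a held-out cell
#' type shrinks as more reference cell types are pooled. Each draw picks a
#' held-out cell type uniformly, a pool size uniformly from 1 to n-1, and a
#' uniform random subset of the remaining cell types of that size; the
#' unique-peak fraction of the held-out set against the pooled subset is
#' recorded. Draws are aggregated per pool size into a weighted mean and
#' standard deviation, each draw weighted inversely to the number of draws
#' sharing its (held-out cell, pool size) combination, so that no held-out
#' cell dominates a size.
#'
#' @param peak_sets Named (or unnamed) list of peak sets, one per cell type,
#'   each a vector of bin indices. At least 4 cell types are required.
#' @param n_samples Number of Monte Carlo draws (default 3000).
#' @param seed Integer seed.
#' @return data.frame with columns \code{n_cells} (pool size),
#'   \code{weighted_mean}, \code{weighted_std} and \code{n_draws}.
#' @export
unique_peak_curve <- function(peak_sets, n_samples = 3000L, seed = 1L) {
  n <- length(peak_sets)
  if (n < 4L) stop("need at least 4 cell types, got ", n)
  if (any(lengths(peak_sets) == 0L)) stop("every cell type needs >= 1 peak")
  set.seed(seed)
  held <- sample.int(n, n_samples, replace = TRUE)
  size <- sample.int(n - 1L, n_samples, replace = TRUE)
  frac <- numeric(n_samples)
  for (d in seq_len(n_samples)) {
    others <- setdiff(seq_len(n), held[d])
    pool <- sample(others, size[d])
    b <- unique(unlist(peak_sets[pool], use.names = FALSE))
    frac[d] <- fraction_unique_peaks(peak_sets[[held[d]]], b)
  }
  out <- lapply(sort(unique(size)), function(s) {
    idx <- which(size == s)
    w <- 1 / table(held[idx])[as.character(held[idx])]
    w <- as.numeric(w)
    mu <- sum(w * frac[idx]) / sum(w)
    sd_w <- sqrt(sum(w * (frac[idx] - mu)^2) / sum(w))
    data.frame(n_cells = s, weighted_mean = mu, weighted_std = sd_w,
               n_draws = length(idx))
  })
  do.call(rbind, out)
}
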