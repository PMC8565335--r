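#' Per-label imbalance summary
#'
#' Computes, for a binary instance-by-label matrix, each label's imbalance
#' ratio IRLbl (the largest label count divided by this label's count, so the
#' most frequent label has IRLbl 1) and the mean imbalance ratio meanIR across
#' labels. Labels whose IRLbl exceeds meanIR are the oversampling candidates.
#'
#' @param labels Binary matrix, instances x labels (column names used as label
#'   names; unnamed columns are numbered).
#' @return Object of class \code{imbalance_summary} with \code{label_counts},
#'   \code{irlbl} and \code{mean_ir}.
#' @export
imbalance_summary <- function(labels) {
  labels <- as.matrix(labels)
  if (is.null(colnames(labels)))
    colnames(labels) <- paste0("label", seq_len(ncol(labels)))
  counts <- colSums(labels != 0)
  zero <- names(counts)[counts == 0]
  if (length(zero))
    stop("label(s) with zero positive instances: ",
         paste(zero, collapse = ", "))
  irlbl <- max(counts) / counts
  structure(list(label_counts = counts, irlbl = irlbl,
                 mean_ir = mean(irlbl)),
            class = "imbalance_summary")
}

#' @export
print.imbalance_summary <- function(x, ...) {
  cat(sprintf("imbalance_summary: %d labels, meanIR %.3f\n",
              length(x$irlbl), x$mean_ir))
  print(data.frame(count = x$label_counts, IRLbl = x$irlbl))
  invisible(x)
}

#' Oversampling quota per under-represented label
#'
#' For every label whose IRLbl strictly exceeds meanIR, the number of extra
#' instances to draw is \code{floor(10 * (IRLbl(l) / meanIR) * count(l))};
#' labels at or below meanIR get no quota and are absent from the result.
#'
#' @param summary An \code{\link{imbalance_summary}}.
#' @return Named integer vector of resample counts (possibly empty).
#' @export
oversample_counts <- function(summary) {
  stopifnot(inherits(summary, "imbalance_summary"))
  qualifying <- summary$irlbl > summary$mean_ir
  k <- floor(10 * (summary$irlbl[qualifying] / summary$mean_ir) *
               summary$label_counts[qualifying])
  stats::setNames(as.integer(k), names(summary$irlbl)[qualifying])
}

#' Oversample instances of under-represented labels
#'
#' Returns the original instance indices followed by, for each qualifying
#' label, its quota of indices drawn uniformly with replacement from the
#' instances positive for that label. Deterministic under a fixed seed.
#'
#' @param instance_idx Instance indices aligned with the rows of
#'   \code{labels}.
#' @param labels Binary instances x labels matrix (same rows as
#'   \code{instance_idx}).
#' @param summary \code{\link{imbalance_summary}} computed from
#'   \code{labels}.
#' @param seed Integer seed.
#' @return Integer vector of instance indices (original + oversampled).
#' @export
oversample_instances <- function(instance_idx, labels, summary, seed = 1L) {
  labels <- as.matrix(labels)
  if (length(instance_idx) != nrow(labels))
    stop("instance_idx not aligned with labels")
  if (is.null(colnames(labels)))
    colnames(labels) <- paste0("label", seq_len(ncol(labels)))
  quota <- oversample_counts(summary)
  set.seed(seed)
  extra <- lapply(names(quota), function(l) {
    pos <- instance_idx[labels[, l] != 0]
    pos[sample.int(length(pos), quota[[l]], replace = TRUE)]
  })
  c(instance_idx, unlist(extra, use.names = FALSE))
}

#' Undersample negatives for a single-target model
#'
#' Keeps all positives and subsamples negatives without replacement down to
#' \code{ratio} times the number of positives (all negatives are kept when
#' fewer are available).
#'
#' @param positive_idx,negative_idx Instance indices.
#' @param ratio Maximum negative:positive ratio (default 10).
#' @param seed Integer seed.
#' @return Integer vector: positives followed by the retained negatives.
#' @export
undersample_single_target <- function(positive_idx, negative_idx, ratio = 10,
                                      seed = 1L) {
  stopifnot(ratio > 0)
  quota <- min(length(negative_idx), floor(ratio * length(positive_idx)))
  set.seed(seed)
  kept <- if (quota == length(negative_idx)) negative_idx
          else negative_idx[sample.int(length(negative_idx), quota)]
  c(positive_idx, kept)
}
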