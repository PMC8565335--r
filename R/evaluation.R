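check_scored <- function(scores, truth) {
  if (length(scores) != length(truth)) stop("scores and truth differ in length")
  if (!all(truth %in% c(0, 1))) stop("truth must be binary")
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  if (n_pos == 0L || n_neg == 0L)
    stop("degenerate truth: need at least one positive and one negative")
  list(n_pos = n_pos, n_neg = n_neg)
}

# Ranked confusion counts with ties grouped: one row per distinct score,
# processed from the highest score down.
ranked_counts <- function(scores, truth) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- truth[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)[!duplicated(grp, fromLast = TRUE)]
  n <- seq_along(s)[!duplicated(grp, fromLast = TRUE)]
  list(tp = tp, fp = n - tp)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) estimator: thresholds sweep the distinct
#' scores from high to low with ties grouped, and each threshold contributes
#' its precision weighted by the recall it adds. A constant scorer therefore
#' scores the positive prevalence, and a perfect ranking scores 1.
#'
#' @param scores Numeric prediction scores.
#' @param truth Binary ground truth (0/1), same length.
#' @return auPRC in (0, 1\].
#' @export
auprc <- function(scores, truth) {
  info <- check_scored(scores, truth)
  rc <- ranked_counts(scores, truth)
  recall <- rc$tp / info$n_pos
  precision <- rc$tp / (rc$tp + rc$fp)
  sum(diff(c(0, recall)) * precision)
}

#' Standardized partial AUC at a false-positive-rate cutoff
#'
#' Area under the ROC curve restricted to FPR in \[0, \code{fpr_max}\]
#' (trapezoidal, ties grouped, linear interpolation at the cutoff), optionally
#' standardized by the McClish transformation
#' \deqn{\frac{1}{2}\left(1 + \frac{pAUC - pAUC_{random}}{pAUC_{perfect} -
#' pAUC_{random}}\right)}
#' which maps a random classifier to 0.5 and a perfect one to 1.
#'
#' @param scores Numeric prediction scores.
#' @param truth Binary ground truth (0/1).
#' @param fpr_max FPR cutoff (default 0.05).
#' @param standardize Apply the McClish transformation (default TRUE); with
#'   \code{standardize = FALSE} and \code{fpr_max = 1} this is the full AUC.
#' @return Partial AUC (standardized by default).
#' @export
partial_auc <- function(scores, truth, fpr_max = 0.05, standardize = TRUE) {
  stopifnot(fpr_max > 0, fpr_max <= 1)
  info <- check_scored(scores, truth)
  rc <- ranked_counts(scores, truth)
  fpr <- c(0, rc$fp / info$n_neg)
  tpr <- c(0, rc$tp / info$n_pos)
  # clip the ROC polygon at fpr_max with linear interpolation
  area <- 0
  for (j in seq_len(length(fpr) - 1L)) {
    x0 <- fpr[j]; x1 <- fpr[j + 1L]
    y0 <- tpr[j]; y1 <- tpr[j + 1L]
    if (x0 >= fpr_max) break
    if (x1 > fpr_max) {
      y1 <- y0 + (y1 - y0) * (fpr_max - x0) / (x1 - x0)
      x1 <- fpr_max
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  if (!standardize) return(area)
  p_perfect <- fpr_max
  p_random <- fpr_max^2 / 2
  0.5 * (1 + (area - p_random) / (p_perfect - p_random))
}

#' Jaccard index of two binary tracks
#'
#' Intersection over union of the positive bins; defined as 0 when both
#' tracks are empty.
#'
#' @param track_a,track_b \code{\link{binned_track}} objects on the same grid.
#' @return Jaccard index in \[0, 1\].
#' @export
jaccard <- function(track_a, track_b) {
  stopifnot(inherits(track_a, "binned_track"),
            inherits(track_b, "binned_track"))
  if (!identical(track_a$grid, track_b$grid))
    stop("tracks are on different grids")
  a <- track_a$values == 1L
  b <- track_b$values == 1L
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

#' Exact Shapley values over assay subsets
#'
#' Given the performance of every subset of a set of assays (e.g. held-out
#' auPRC of models whose similarity vector uses that subset), computes each
#' assay's exact Shapley value: its performance contribution averaged over
#' all orders in which assays could be added.
#'
#' @param performance Named numeric vector giving the value of every subset.
#'   Names are subset keys: assay names sorted and joined with \code{"+"}, with
#'   \code{""} for the empty set (e.g. \code{c("" = 0, "a" = 1, "b" = 0,
#'   "a+b" = 1)}).
#' @param assays Character vector of assay names; defaults to the assays
#'   appearing in the largest subset key.
#' @return Named numeric vector of Shapley values, one per assay.
#' @export
shapley_over_assays <- function(performance, assays = NULL) {
  keys <- names(performance)
  if (is.null(keys)) stop("performance must be a named vector")
  if (is.null(assays)) {
    assays <- unique(unlist(strsplit(keys[nchar(keys) > 0], "+", fixed = TRUE)))
    assays <- sort(assays)
  }
  n <- length(assays)
  subset_key <- function(members) paste(sort(members), collapse = "+")
  value <- function(members) {
    k <- subset_key(members)
    idx <- match(k, keys)   # positional: "[[" cannot take an empty-string key
    if (is.na(idx))
      stop("performance missing for subset: '", k, "'")
    unname(performance[[idx]])
  }
  phi <- stats::setNames(numeric(n), assays)
  # enumerate subsets S not containing the assay; weight |S|!(n-|S|-1)!/n!
  all_subsets <- lapply(0:(2^n - 1), function(mask)
    assays[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
  for (a in assays) {
    for (s in all_subsets) {
      if (a %in% s) next
      w <- factorial(length(s)) * factorial(n - length(s) - 1) / factorial(n)
      phi[a] <- phi[a] + w * (value(c(s, a)) - value(s))
    }
  }
  phi
}

#' Select evaluation regions for one target
#'
#' Restricts evaluation to regions where prediction is non-trivial: 200 bp
#' bins that either overlap a ChIP-seq peak for the target in at least one
#' reference cell type, or overlap an accessibility peak from at least one
#' cell type that has measured that target. Outside this set a
#' reference-based predictor is defined to output 0.
#'
#' @param dataset A \code{\link{build_dataset}} dataset.
#' @param target ChIP target name.
#' @param regions Candidate global bin indices (default: the dataset's test
#'   partition).
#' @return The subset of \code{regions} satisfying the rule.
#' @export
select_test_regions <- function(dataset, target,
                                regions = dataset$region_index[
                                  dataset$partition == "test"]) {
  cells_with_target <- Filter(function(cl) {
    paste(cl, target, sep = "|") %in% names(dataset$tracks)
  }, dataset$cells)
  if (length(cells_with_target) == 0L)
    stop("no cell type carries target ", target)
  keep <- rep(FALSE, length(regions))
  for (cl in cells_with_target) {
    keep <- keep | get_track(dataset, cl, target)$values[regions] == 1L |
      get_track(dataset, cl, dataset$accessibility_assay)$values[regions] == 1L
  }
  regions[keep]
}
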