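# Independent brute-force oracles used to check the package's vectorized
# implementations. These deliberately share no code with the package paths
# they verify.

toy_grid <- function(bins = 200L, bin_size = 200L, n_chrom = 1L) {
  lens <- rep(bins * bin_size, n_chrom)
  names(lens) <- paste0("chr", seq_len(n_chrom))
  bin_grid(lens, bin_size = bin_size)
}

random_track <- function(grid, p = 0.3, cell = "c", assay = "accessibility") {
  binned_track(cell, assay, stats::rbinom(grid$total_bins, 1, p), grid)
}

# per-bin any-overlap check for binarization; intervals as a data.frame with
# 0-based half-open chrom/start/end
oracle_binarize <- function(intervals, grid) {
  values <- integer(grid$total_bins)
  chroms <- rep(names(grid$n_bins), grid$n_bins)
  local <- unlist(lapply(unname(grid$n_bins), seq_len)) - 1L
  for (g in seq_len(grid$total_bins)) {
    b_start <- local[g] * grid$bin_size
    b_end <- b_start + grid$bin_size
    for (r in seq_len(nrow(intervals))) {
      if (intervals$chrom[r] == chroms[g] &&
          intervals$start[r] < b_end && intervals$end[r] > b_start) {
        values[g] <- 1L
        break
      }
    }
  }
  values
}

# ring-enumeration similarity oracle on a single-chromosome grid;
# bins beyond [1, L] are treated as 0 in both tracks
oracle_casv <- function(i_local, q, k, L, sizes = c(1L, 5L, 19L, 59L)) {
  val <- function(v, idx) ifelse(idx >= 1 & idx <= L,
                                 v[pmax(pmin(idx, L), 1L)], 0L)
  prev <- integer(0)
  pos <- agr <- numeric(length(sizes))
  for (z in seq_along(sizes)) {
    h <- (sizes[z] - 1L) / 2L
    win <- (i_local - h):(i_local + h)
    ring <- setdiff(win, prev)
    qv <- val(q, ring); kv <- val(k, ring)
    pos[z] <- sum(qv * kv) / length(ring)
    agr[z] <- sum(qv == kv) / length(ring)
    prev <- win
  }
  c(pos, agr)
}

# exhaustive-threshold precision-recall area
oracle_auprc <- function(scores, truth) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  area <- 0
  n_pos <- sum(truth == 1)
  for (t in thresholds) {
    called <- scores >= t
    precision <- sum(truth[called] == 1) / sum(called)
    recall <- sum(truth[called] == 1) / n_pos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# exhaustive-threshold ROC polygon clipped to an FPR band (geometry only;
# no standardization)
oracle_pauc_raw <- function(scores, truth, fpr_max) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  fpr <- 0; tpr <- 0
  pts <- data.frame(fpr = 0, tpr = 0)
  for (t in thresholds) {
    called <- scores >= t
    pts <- rbind(pts, data.frame(
      fpr = sum(truth[called] == 0) / sum(truth == 0),
      tpr = sum(truth[called] == 1) / sum(truth == 1)))
  }
  area <- 0
  for (j in seq_len(nrow(pts) - 1)) {
    x0 <- pts$fpr[j]; x1 <- pts$fpr[j + 1]
    y0 <- pts$tpr[j]; y1 <- pts$tpr[j + 1]
    if (x0 >= fpr_max) break
    if (x1 > fpr_max) {
      y1 <- y0 + (y1 - y0) * (fpr_max - x0) / (x1 - x0)
      x1 <- fpr_max
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  area
}

# rank-statistic (Mann-Whitney) full AUC
oracle_auc_rank <- function(scores, truth) {
  r <- rank(scores)
  n_pos <- sum(truth == 1); n_neg <- sum(truth == 0)
  (sum(r[truth == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Shapley values by explicit enumeration of all n! orders
oracle_shapley <- function(performance, assays) {
  n <- length(assays)
  perms <- gtools_permutations(n)
  val <- function(s) performance[[match(paste(sort(s), collapse = "+"),
                                        names(performance))]]
  phi <- stats::setNames(numeric(n), assays)
  for (p in seq_len(nrow(perms))) {
    before <- character(0)
    for (j in seq_len(n)) {
      a <- assays[perms[p, j]]
      phi[a] <- phi[a] + val(c(before, a)) - val(before)
      before <- c(before, a)
    }
  }
  phi / nrow(perms)
}

# all permutations of 1..n (tiny n only)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# random subset-performance game over the given assays
random_game <- function(assays) {
  n <- length(assays)
  keys <- unlist(lapply(0:n, function(k)
    if (k == 0) "" else apply(utils::combn(sort(assays), k), 2,
                              paste, collapse = "+")))
  stats::setNames(stats::runif(length(keys)), keys)
}

# tiny two-cell dataset used across model tests
tiny_dataset <- function(seed = 42L, bins = 400L, n_cells = 3L,
                         n_targets = 1L) {
  set.seed(seed)
  grid <- toy_grid(bins = bins / 4L, n_chrom = 4L)
  cells <- paste0("cell", seq_len(n_cells))
  targets <- paste0("target", seq_len(n_targets))
  tracks <- list()
  for (cl in cells) {
    acc <- stats::rbinom(grid$total_bins, 1, 0.3)
    tracks[[paste(cl, "accessibility", sep = "|")]] <-
      binned_track(cl, "accessibility", acc, grid)
    for (tg in targets) {
      pk <- stats::rbinom(grid$total_bins, 1, ifelse(acc == 1, 0.7, 0.05))
      tracks[[paste(cl, tg, sep = "|")]] <- binned_track(cl, tg, pk, grid)
    }
  }
  build_dataset(unname(tracks), grid,
                split = split_config(valid = "chr2", test = "chr3",
                                     train_valid = "chr4",
                                     exclude = character(0)))
}
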