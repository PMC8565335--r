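test_that("read_peak_file parses BED3+ with 0-based half-open coordinates", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=peaks", "# a comment",
               "chr1\t250\t450\tpeakA\t100",
               "chr2\t0\t200"), path)
  gr <- read_peak_file(path)
  expect_equal(length(gr), 2L)
  expect_equal(as.character(GenomicRanges::seqnames(gr)), c("chr1", "chr2"))
  expect_equal(GenomicRanges::start(gr), c(251L, 1L))  # GRanges is 1-based
  expect_equal(GenomicRanges::end(gr), c(450L, 200L))
})

test_that("read_peak_file handles narrowPeak, empty files and bad lines", {
  np <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t250\t450\t.\t0\t.\t5.1\t3.2\t2.2\t100", np)
  gr <- read_peak_file(np, format = "narrowPeak")
  expect_equal(GenomicRanges::start(gr), 251L)
  expect_equal(ncol(S4Vectors::mcols(gr)), 0L)  # stats columns ignored

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_equal(length(read_peak_file(empty)), 0L)

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t450\t250"), bad)
  expect_error(read_peak_file(bad), "line 2")
  writeLines("chr1\t1.5\t200", bad)
  expect_error(read_peak_file(bad), "non-integer")
  writeLines("chr1\t100", bad)
  expect_error(read_peak_file(bad), "at least 3")
})

test_that("bin_and_binarize marks bins with >= 1 bp overlap", {
  g <- bin_grid(c(chr1 = 2000))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(251, 450)) # 250-450
  expect_equal(which(bin_and_binarize(gr, g)$values == 1L), c(2L, 3L))
  # half-open: [200, 400) touches only the second bin
  gr2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 400))
  expect_equal(which(bin_and_binarize(gr2, g)$values == 1L), 2L)
  expect_equal(sum(bin_and_binarize(empty_gr <- GenomicRanges::GRanges(),
                                    g)$values), 0L)
  expect_warning(
    tr <- bin_and_binarize(GenomicRanges::GRanges(
      c("chr1", "chrUn"), IRanges::IRanges(c(1, 1), c(100, 100))), g),
    "chrUn")
  expect_equal(which(tr$values == 1L), 1L)
})

test_that("binarization equals a per-bin brute-force overlap check", {
  set.seed(11)
  g <- bin_grid(c(chr1 = 4000, chr2 = 2100), bin_size = 200)
  for (rep in 1:20) {
    n <- sample(1:15, 1)
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    start <- sapply(chrom, function(cl) sample(0:(g$chrom_lengths[[cl]] - 2), 1))
    width <- sample(1:700, n, replace = TRUE)
    end <- pmin(start + width, g$chrom_lengths[chrom])
    ivl <- data.frame(chrom = chrom, start = start, end = end)
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
    expect_equal(bin_and_binarize(gr, g)$values, oracle_binarize(ivl, g))
  }
})

test_that("consensus_merge applies the printed replicate rules", {
  g <- bin_grid(c(chr1 = 1200))
  mk <- function(v) binned_track("c", "a", v, g)
  r1 <- mk(c(1, 0, 0, 0, 1, 0)); r2 <- mk(c(0, 1, 0, 0, 1, 0))
  r3 <- mk(c(0, 1, 1, 0, 1, 0)); r4 <- mk(c(0, 0, 1, 0, 0, 0))
  expect_equal(consensus_merge(list(r1)), r1)                 # identity
  expect_equal(consensus_merge(list(r1, r2))$values,
               c(1, 1, 0, 0, 1, 0))                           # union
  expect_equal(consensus_merge(list(r1, r2, r3))$values,
               c(0, 1, 0, 0, 1, 0))                           # >= 2 of 3
  # 4 replicates: threshold ceil(0.25 * 4) = 1, i.e. union again
  expect_equal(consensus_merge(list(r1, r2, r3, r4))$values,
               c(1, 1, 1, 0, 1, 0))
  # 8 replicates: threshold 2
  expect_equal(consensus_merge(rep(list(r1), 7))$values, r1$values)
  g2 <- bin_grid(c(chr1 = 1400))
  expect_error(consensus_merge(list(r1, binned_track("c", "a",
                                                     rep(0, 7), g2))),
               "different grids")
})

test_that("consensus_merge is monotone in a superset replicate for n <= 3", {
  set.seed(5)
  g <- bin_grid(c(chr1 = 5000))
  for (n in 1:3) {
    reps <- lapply(seq_len(n), function(i) random_track(g, 0.3))
    merged <- consensus_merge(reps)
    sup_values <- as.integer(merged$values | stats::rbinom(g$total_bins, 1, 0.2))
    sup <- binned_track("c", "accessibility", sup_values, g)
    merged2 <- consensus_merge(c(reps, list(sup)))
    expect_true(all(merged2$values >= merged$values))
  }
})

test_that("build_dataset indexes informative bins and splits by chromosome", {
  g <- bin_grid(c(chr1 = 1000, chr7 = 1000, chr8 = 1000, chrX = 1000))
  zeros <- integer(g$total_bins)
  acc1 <- zeros; acc1[c(1, 6, 11, 16)] <- 1L  # one bin per chromosome
  acc2 <- zeros; acc2[2] <- 1L
  tg1 <- zeros; tg1[6] <- 1L
  tg2 <- zeros; tg2[2] <- 1L
  tracks <- list(binned_track("A", "accessibility", acc1, g),
                 binned_track("A", "target1", tg1, g),
                 binned_track("B", "accessibility", acc2, g),
                 binned_track("B", "target1", tg2, g))
  ds <- build_dataset(tracks, g, split = split_config(train_valid = NULL))
  expect_equal(ds$region_index, c(1L, 2L, 6L, 11L))  # chrX bin 16 excluded
  expect_equal(as.character(ds$partition), c("train", "train", "valid", "test"))

  # all-zero tracks: nothing informative
  tz <- list(binned_track("A", "accessibility", zeros, g),
             binned_track("A", "target1", zeros, g),
             binned_track("B", "accessibility", zeros, g),
             binned_track("B", "target1", zeros, g))
  expect_error(build_dataset(tz, g), "no informative regions")

  # a cell without accessibility is rejected
  tracks2 <- c(tracks, list(binned_track("C", "target1", tg1, g)))
  expect_warning(ds2 <- build_dataset(tracks2, g), "rejecting cell")
  expect_false("C" %in% ds2$cells)
})

test_that("BED round trip reproduces a track exactly", {
  set.seed(21)
  g <- bin_grid(c(chr1 = 4000, chr2 = 2100))
  tr <- random_track(g, 0.35)
  path <- withr::local_tempfile(fileext = ".bed")
  write_track_bed(tr, path)
  back <- bin_and_binarize(read_peak_file(path), g,
                           cell = tr$cell, assay = tr$assay)
  expect_equal(back$values, tr$values)
  # empty track round trip
  tr0 <- binned_track("c", "accessibility", integer(g$total_bins), g)
  write_track_bed(tr0, path)
  expect_equal(sum(bin_and_binarize(read_peak_file(path), g)$values), 0L)
})

test_that("dataset container round trips through mtx + JSON sidecar", {
  ds <- tiny_dataset(seed = 3)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "regions.mtx.gz")))
  ds2 <- read_dataset(dir)
  expect_equal(ds2$region_index, ds$region_index)
  expect_equal(as.character(ds2$partition), as.character(ds$partition))
  expect_equal(names(ds2$tracks), names(ds$tracks))
  for (nm in names(ds$tracks))
    expect_equal(ds2$tracks[[nm]]$values[ds$region_index],
                 ds$tracks[[nm]]$values[ds$region_index])
})

test_that("read_chrom_sizes builds the expected grid", {
  path <- withr::local_tempfile()
  writeLines(c("chr1\t1000", "chr2\t450"), path)
  g <- read_chrom_sizes(path)
  expect_equal(unname(g$n_bins), c(5L, 3L))
  expect_equal(g$total_bins, 8L)
  expect_equal(global_bin(g, "chr2", 0L), 6L)
  expect_equal(bin_coords(g, 8L),
               data.frame(chrom = "chr2", start = 400, end = 450))
})

test_that("fraction_unique_peaks evaluates the set-difference fraction", {
  expect_equal(fraction_unique_peaks(c(1, 2), c(1, 2, 3)), 0)      # A in B
  expect_equal(fraction_unique_peaks(1:4, 3:5), 0.5)
  expect_equal(fraction_unique_peaks(1:3, integer(0)), 1)          # B empty
  expect_error(fraction_unique_peaks(integer(0), 1:3), "empty")
  # monotone non-increasing as the reference pool grows
  set.seed(9)
  for (i in 1:20) {
    a <- sample(1:50, 20); b1 <- sample(1:50, 15); b2 <- sample(1:50, 15)
    expect_gte(fraction_unique_peaks(a, b1),
               fraction_unique_peaks(a, union(b1, b2)))
  }
})

test_that("unique_peak_curve matches exhaustive enumeration on 4 cell types", {
  # cells: 10 shared bins + partially overlapping private blocks
  sets <- list(c(1:10, 11:15), c(1:10, 13:20), c(1:10, 18:25),
               c(1:10, 23:30))
  # exhaustive expectation per pool size: average over held-out cells and
  # over all subsets of that size of the unique fraction
  exhaustive <- sapply(1:3, function(s) {
    vals <- c()
    for (h in 1:4) {
      others <- setdiff(1:4, h)
      combos <- utils::combn(others, s)
      for (j in seq_len(ncol(combos))) {
        b <- unique(unlist(sets[combos[, j]]))
        vals <- c(vals, length(setdiff(sets[[h]], b)) / length(sets[[h]]))
      }
    }
    mean(vals)
  })
  curve <- unique_peak_curve(sets, n_samples = 3000, seed = 4)
  expect_equal(curve$n_cells, 1:3)
  expect_true(all(abs(curve$weighted_mean - exhaustive) < 0.02))
  # the mechanism behind the downward trend: pooled references catch more
  expect_true(all(diff(curve$weighted_mean) <= 1e-9))

  # identical cell types: every draw is 0
  same <- rep(list(1:10), 4)
  expect_true(all(unique_peak_curve(same, 200, seed = 1)$weighted_mean == 0))
  # determinism
  expect_identical(unique_peak_curve(sets, 500, seed = 7),
                   unique_peak_curve(sets, 500, seed = 7))
  expect_error(unique_peak_curve(sets[1:3]), "at least 4")
})
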