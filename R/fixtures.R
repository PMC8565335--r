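#' Configuration for the synthetic multi-cell-type fixture generator
#'
#' The generator emulates the statistical structure the model relies on:
#' several reference cell types share a common backbone of accessible 200 bp
#' bins plus cell-specific accessible bins; ChIP target peaks occur
#' preferentially inside accessible bins (so accessibility is informative of
#' the epigenetic events, but imperfectly); and a query context whose true
#' accessibility is a per-bin mixture of the reference cells'. Bernoulli flip
#' noise models assay noise on the *observed* accessibility tracks; target
#' peaks and the query truth are generated from the pre-noise (true)
#' accessibility.
#'
#' @param n_chromosomes Number of synthetic chromosomes, named
#'   \code{chr1..chrN} (default 10, so the standard chr7/chr8-9 split
#'   applies).
#' @param bins_per_chromosome Bins per chromosome (default 2000; 20,000 bins
#'   total with the default chromosome count).
#' @param n_reference_cells Reference cell types (default 5).
#' @param n_targets ChIP targets (default 1), named \code{target1..}.
#' @param shared_accessibility_rate Fraction of bins accessible in every cell
#'   (the shared backbone; default 0.10).
#' @param specific_accessibility_rate Additional per-cell accessible fraction
#'   (default 0.05).
#' @param peak_given_accessible P(target peak | bin accessible) (default 0.6).
#' @param peak_given_inaccessible P(target peak | bin inaccessible)
#'   (default 0.02). Must be below \code{peak_given_accessible}.
#' @param query_mixture Weights over reference cells from which the query's
#'   true accessibility is drawn per bin; must sum to 1. Default: 0.6 on the
#'   first cell, the rest spread evenly -- a query resembling one reference
#'   more than the others.
#' @param flip_noise Per-bin Bernoulli flip rate applied to observed
#'   accessibility (default 0.05).
#' @param bin_size Bin width in bp (default 200).
#' @param seed Integer seed; the fixture is fully determined by it.
#' @return List of class \code{fixture_config}.
#' @export
fixture_config <- function(n_chromosomes = 10L, bins_per_chromosome = 2000L,
                           n_reference_cells = 5L, n_targets = 1L,
                           shared_accessibility_rate = 0.10,
                           specific_accessibility_rate = 0.05,
                           peak_given_accessible = 0.6,
                           peak_given_inaccessible = 0.02,
                           query_mixture = NULL,
                           flip_noise = 0.05,
                           bin_size = 200L,
                           seed = 1L) {
  if (is.null(query_mixture)) {
    query_mixture <- rep(0.4 / (n_reference_cells - 1), n_reference_cells)
    query_mixture[1L] <- 0.6
  }
  rates <- c(shared_accessibility_rate, specific_accessibility_rate,
             peak_given_accessible, peak_given_inaccessible, flip_noise,
             query_mixture)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (abs(sum(query_mixture) - 1) > 1e-8) stop("query_mixture must sum to 1")
  if (length(query_mixture) != n_reference_cells)
    stop("query_mixture length must equal n_reference_cells")
  if (peak_given_accessible <= peak_given_inaccessible)
    stop("peak_given_accessible must exceed peak_given_inaccessible")
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 bins_per_chromosome = as.integer(bins_per_chromosome),
                 n_reference_cells = as.integer(n_reference_cells),
                 n_targets = as.integer(n_targets),
                 shared_accessibility_rate = shared_accessibility_rate,
                 specific_accessibility_rate = specific_accessibility_rate,
                 peak_given_accessible = peak_given_accessible,
                 peak_given_inaccessible = peak_given_inaccessible,
                 query_mixture = query_mixture,
                 flip_noise = flip_noise,
                 bin_size = as.integer(bin_size),
                 seed = as.integer(seed)),
            class = "fixture_config")
}

#' Generate a seeded synthetic multi-cell-type dataset
#'
#' @param config A \code{\link{fixture_config}}.
#' @param split A \code{\link{split_config}} used to partition the dataset
#'   (default: standard split with no train_valid chromosome; pass one with
#'   \code{train_valid} set when training with early stopping).
#' @return List with \code{dataset} (a \code{\link{build_dataset}} dataset
#'   over cells \code{cell1..} with assays \code{accessibility} and
#'   \code{target1..}), \code{query} (named list with the query's observed
#'   \code{accessibility} track), \code{truth} (named list of the query's
#'   true target tracks), \code{query_true_accessibility}, and \code{config}.
#' @export
generate_fixture <- function(config = fixture_config(),
                             split = split_config(train_valid = NULL)) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(config$seed)
  lens <- rep(config$bins_per_chromosome * config$bin_size,
              config$n_chromosomes)
  names(lens) <- paste0("chr", seq_len(config$n_chromosomes))
  grid <- bin_grid(lens, bin_size = config$bin_size)
  nb <- grid$total_bins
  cells <- paste0("cell", seq_len(config$n_reference_cells))
  targets <- paste0("target", seq_len(config$n_targets))

  backbone <- stats::rbinom(nb, 1L, config$shared_accessibility_rate)
  true_acc <- lapply(cells, function(cl) {
    extra <- stats::rbinom(nb, 1L, config$specific_accessibility_rate)
    as.integer(backbone | extra)
  })
  names(true_acc) <- cells
  flip <- function(v) {
    f <- stats::rbinom(nb, 1L, config$flip_noise)
    as.integer(xor(v, f))
  }
  peaks_from_acc <- function(acc) {
    p <- ifelse(acc == 1L, config$peak_given_accessible,
                config$peak_given_inaccessible)
    stats::rbinom(nb, 1L, p)
  }

  tracks <- list()
  for (cl in cells) {
    tracks[[paste(cl, "accessibility", sep = "|")]] <-
      binned_track(cl, "accessibility", flip(true_acc[[cl]]), grid)
    for (tg in targets) {
      tracks[[paste(cl, tg, sep = "|")]] <-
        binned_track(cl, tg, peaks_from_acc(true_acc[[cl]]), grid)
    }
  }

  src <- sample.int(config$n_reference_cells, nb, replace = TRUE,
                    prob = config$query_mixture)
  q_true <- do.call(cbind, true_acc)[cbind(seq_len(nb), src)]
  q_obs <- flip(q_true)
  truth <- lapply(targets, function(tg)
    binned_track("query", tg, peaks_from_acc(q_true), grid))
  names(truth) <- targets

  dataset <- build_dataset(unname(tracks), grid, split = split)
  list(dataset = dataset,
       query = list(accessibility = binned_track("query", "accessibility",
                                                 q_obs, grid)),
       truth = truth,
       query_true_accessibility = binned_track("query", "true_accessibility",
                                               q_true, grid),
       config = config)
}

#' Write a fixture as a plain-text file tree
#'
#' One BED3 file of positive bins per (cell, assay), one per query assay and
#' per truth target, a chrom.sizes TSV, and a manifest JSON recording the
#' configuration. Reading the BEDs back through \code{\link{read_peak_file}}
#' and \code{\link{bin_and_binarize}} reproduces the tracks exactly.
#'
#' @param fixture As returned by \code{\link{generate_fixture}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- fixture$dataset
  for (tr in ds$tracks)
    write_track_bed(tr, file.path(dir, paste0(tr$cell, "_", tr$assay, ".bed")))
  for (a in names(fixture$query))
    write_track_bed(fixture$query[[a]],
                    file.path(dir, paste0("query_", a, ".bed")))
  for (tg in names(fixture$truth))
    write_track_bed(fixture$truth[[tg]],
                    file.path(dir, paste0("query_truth_", tg, ".bed")))
  utils::write.table(
    data.frame(names(ds$grid$chrom_lengths), ds$grid$chrom_lengths),
    file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  manifest <- c(unclass(fixture$config),
                list(cells = ds$cells, targets = ds$targets,
                     accessibility_assay = ds$accessibility_assay))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
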