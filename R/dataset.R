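#' Chromosome split configuration
#'
#' Defines the chromosome-level partition used to build a
#' \code{\link{build_dataset}} dataset: all binned regions on the validation
#' chromosome(s) go to \code{valid}, the test chromosomes to \code{test},
#' an optional train-validation chromosome (used for early-stopping
#' evaluation during training) to \code{train_valid}, and the remainder to
#' \code{train}. Sex and mitochondrial chromosomes are excluded entirely.
#'
#' @param valid Validation chromosomes (default \code{"chr7"}).
#' @param test Test chromosomes (default \code{c("chr8", "chr9")}).
#' @param train_valid Train-validation chromosomes, or \code{NULL} to fold
#'   them into \code{train} (default \code{"chr22"}; pass \code{NULL} when
#'   early stopping is not used).
#' @param exclude Chromosomes removed from the dataset entirely
#'   (default \code{c("chrX", "chrY", "chrM")}).
#' @return A list of class \code{split_config}.
#' @export
split_config <- function(valid = "chr7", test = c("chr8", "chr9"),
                         train_valid = "chr22",
                         exclude = c("chrX", "chrY", "chrM")) {
  groups <- list(valid = valid, test = test, train_valid = train_valid)
  all_named <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_named))
    stop("a chromosome appears in more than one split group")
  if (length(intersect(all_named, exclude)))
    stop("excluded chromosomes cannot appear in a split group")
  structure(list(valid = valid, test = test, train_valid = train_valid,
                 exclude = exclude),
            class = "split_config")
}

#' Assemble a multi-cell-type peak dataset
#'
#' Collects binary tracks into a dataset over the bins that carry at least one
#' peak in any track (the region index), and partitions those regions by
#' chromosome into train / valid / test (/ train_valid) sets. Cell types
#' without an accessibility track are rejected with a warning, since the
#' similarity features cannot be computed for them.
#'
#' @param tracks List of \code{\link{binned_track}} objects, all on
#'   \code{grid}.
#' @param grid A \code{\link{bin_grid}}.
#' @param split A \code{\link{split_config}}.
#' @param accessibility_assay Assay name identifying accessibility tracks
#'   (default \code{"accessibility"}).
#' @return An object of class \code{peak_dataset} with elements \code{grid},
#'   \code{tracks} (named \code{cell|assay}), \code{cells}, \code{targets}
#'   (non-accessibility assays), \code{accessibility_assay},
#'   \code{region_index} (sorted global bin indices) and \code{partition}
#'   (factor over \code{region_index} with levels train, valid, test,
#'   train_valid).
#' @export
build_dataset <- function(tracks, grid, split = split_config(),
                          accessibility_assay = "accessibility") {
  stopifnot(inherits(grid, "bin_grid"), inherits(split, "split_config"))
  for (tr in tracks) {
    if (!inherits(tr, "binned_track")) stop("tracks must be binned_track")
    if (!identical(tr$grid, grid)) stop("track grid does not match dataset grid")
  }
  cells <- unique(vapply(tracks, `[[`, character(1), "cell"))
  has_acc <- vapply(cells, function(cl) {
    any(vapply(tracks, function(tr)
      tr$cell == cl && tr$assay == accessibility_assay, logical(1)))
  }, logical(1))
  if (any(!has_acc)) {
    warning("rejecting cell type(s) without an accessibility track: ",
            paste(cells[!has_acc], collapse = ", "))
    tracks <- Filter(function(tr) has_acc[[tr$cell]], tracks)
    cells <- cells[has_acc]
  }
  if (length(cells) < 2L)
    stop("need at least two cell types with accessibility tracks")
  targets <- setdiff(unique(vapply(tracks, `[[`, character(1), "assay")),
                     accessibility_assay)
  if (length(targets) < 1L)
    stop("need at least one ChIP target track")
  names(tracks) <- vapply(tracks, function(tr)
    paste(tr$cell, tr$assay, sep = "|"), character(1))
  if (anyDuplicated(names(tracks)))
    stop("duplicated (cell, assay) track; merge replicates first")

  any_pos <- Reduce(`|`, lapply(tracks, function(tr) tr$values == 1L))
  chroms <- bin_chroms(grid)
  any_pos[chroms %in% split$exclude] <- FALSE
  region_index <- which(any_pos)
  if (length(region_index) == 0L) stop("no informative regions")
  rchrom <- chroms[region_index]
  partition <- rep("train", length(region_index))
  partition[rchrom %in% split$valid] <- "valid"
  partition[rchrom %in% split$test] <- "test"
  if (!is.null(split$train_valid))
    partition[rchrom %in% split$train_valid] <- "train_valid"
  partition <- factor(partition,
                      levels = c("train", "valid", "test", "train_valid"))
  structure(list(grid = grid, tracks = tracks, cells = cells,
                 targets = targets,
                 accessibility_assay = accessibility_assay,
                 region_index = region_index, partition = partition,
                 split = split),
            class = "peak_dataset")
}

#' @export
print.peak_dataset <- function(x, ...) {
  cat(sprintf("peak_dataset: %d cells, %d targets, %d regions\n",
              length(x$cells), length(x$targets), length(x$region_index)))
  print(table(x$partition))
  invisible(x)
}

#' Fetch one track from a dataset
#'
#' @param dataset A \code{peak_dataset}.
#' @param cell,assay Identifiers.
#' @return The \code{\link{binned_track}}, or an error if absent.
#' @export
get_track <- function(dataset, cell, assay) {
  key <- paste(cell, assay, sep = "|")
  tr <- dataset$tracks[[key]]
  if (is.null(tr)) stop("no track for ", key)
  tr
}

#' Binary label matrix over dataset regions
#'
#' @param dataset A \code{peak_dataset}.
#' @param cell Cell type.
#' @param assays Assays to include as columns (default: all targets).
#' @param regions Global bin indices (default: the whole region index).
#' @return Integer matrix, \code{length(regions)} x \code{length(assays)}.
#' @export
region_label_matrix <- function(dataset, cell, assays = dataset$targets,
                                regions = dataset$region_index) {
  m <- vapply(assays, function(a) get_track(dataset, cell, a)$values[regions],
              integer(length(regions)))
  matrix(m, nrow = length(regions), ncol = length(assays),
         dimnames = list(NULL, assays))
}

#' Serialize a dataset to disk
#'
#' Writes the region-by-track binary matrix as a (gzipped) MatrixMarket
#' sparse matrix plus a JSON sidecar carrying the grid, track names, region
#' index and partition, and the split configuration.
#'
#' @param dataset A \code{peak_dataset}.
#' @param dir Output directory (created if needed).
#' @param compress Gzip the matrix file (default TRUE).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(dataset, dir, compress = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mats <- lapply(dataset$tracks, function(tr) tr$values[dataset$region_index])
  m <- Matrix::Matrix(do.call(cbind, mats), sparse = TRUE)
  mtx <- file.path(dir, "regions.mtx")
  Matrix::writeMM(m, mtx)
  if (compress) {
    con_in <- file(mtx, "rb"); con_out <- gzfile(paste0(mtx, ".gz"), "wb")
    while (length(chunk <- readBin(con_in, "raw", 1024^2)) > 0)
      writeBin(chunk, con_out)
    close(con_in); close(con_out); unlink(mtx)
  }
  sidecar <- list(
    bin_size = dataset$grid$bin_size,
    chrom_lengths = as.list(dataset$grid$chrom_lengths),
    track_cells = vapply(dataset$tracks, `[[`, character(1), "cell"),
    track_assays = vapply(dataset$tracks, `[[`, character(1), "assay"),
    cells = dataset$cells,
    targets = dataset$targets,
    accessibility_assay = dataset$accessibility_assay,
    region_index = dataset$region_index,
    partition = as.character(dataset$partition),
    split = unclass(dataset$split),
    matrix_file = if (compress) "regions.mtx.gz" else "regions.mtx")
  jsonlite::write_json(sidecar, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a dataset written by \code{\link{write_dataset}}
#'
#' @param dir Directory containing \code{dataset.json} and the matrix file.
#' @return A \code{peak_dataset}.
#' @export
read_dataset <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "dataset.json"),
                              simplifyVector = TRUE)
  lens <- unlist(side$chrom_lengths)
  grid <- bin_grid(lens, bin_size = side$bin_size)
  m <- as.matrix(Matrix::readMM(file.path(dir, side$matrix_file)))
  region_index <- as.integer(side$region_index)
  cells <- unlist(side$track_cells)
  assays <- unlist(side$track_assays)
  tracks <- lapply(seq_along(cells), function(j) {
    values <- integer(grid$total_bins)
    values[region_index] <- as.integer(m[, j])
    binned_track(cells[j], assays[j], values, grid)
  })
  names(tracks) <- paste(cells, assays, sep = "|")
  split <- split_config(
    valid = unlist(side$split$valid), test = unlist(side$split$test),
    train_valid = if (length(side$split$train_valid))
      unlist(side$split$train_valid) else NULL,
    exclude = unlist(side$split$exclude))
  structure(list(grid = grid, tracks = tracks, cells = side$cells,
                 targets = side$targets,
                 accessibility_assay = side$accessibility_assay,
                 region_index = region_index,
                 partition = factor(side$partition,
                                    levels = c("train", "valid", "test",
                                               "train_valid")),
                 split = split),
            class = "peak_dataset")
}
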