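#' Per-cell-type channel specification
#'
#' Each reference cell type feeds the network through its own channel. The
#' channel input is the cell's binarized ChIP-seq peak vector (one entry per
#' model target available in that cell) concatenated with the similarity
#' vector against the query; the two hidden layers have dimensions
#' \code{floor(input/2)} and \code{max(1, floor(input/4))} with hyperbolic
#' tangent activations.
#'
#' @param cell Cell-type identifier.
#' @param targets_available Ordered ChIP targets measured in this cell and
#'   included in the model.
#' @param casv_length Length of the similarity vector (8 per assay with
#'   default windows).
#' @return Object of class \code{channel_spec} with \code{input_dim},
#'   \code{layer1_dim}, \code{layer2_dim}.
#' @examples
#' channel_spec("K562", "CTCF", 8)$input_dim        # 9
#' channel_spec("K562", paste0("t", 1:250), 8)$input_dim  # 258
#' @export
channel_spec <- function(cell, targets_available, casv_length = 8L) {
  input_dim <- length(targets_available) + as.integer(casv_length)
  structure(list(cell = cell,
                 targets_available = targets_available,
                 casv_length = as.integer(casv_length),
                 input_dim = input_dim,
                 layer1_dim = max(1L, input_dim %/% 2L),
                 layer2_dim = max(1L, input_dim %/% 4L)),
            class = "channel_spec")
}

#' Training configuration
#'
#' @param batch_size Instances per gradient step (default 64).
#' @param max_batches Maximum training batches (default 5000).
#' @param min_batches Batches trained before early stopping may halt
#'   (default 800).
#' @param valid_interval Batches between train-validation evaluations
#'   (default 200).
#' @param valid_sample Instances drawn from the train-validation pool per
#'   evaluation (default 1000).
#' @param patience Consecutive non-improving evaluations tolerated before
#'   halting (default 5).
#' @param min_delta Minimum decrease of the best train-validation loss that
#'   counts as improvement (default 0).
#' @param learning_rate Adam step size (default 1e-3).
#' @param early_stopping Evaluate on the train-validation partition and halt
#'   on plateau (default FALSE).
#' @param seed Integer seed driving initialization, shuffling and sampling.
#' @return List of class \code{training_config}.
#' @export
training_config <- function(batch_size = 64L, max_batches = 5000L,
                            min_batches = 800L, valid_interval = 200L,
                            valid_sample = 1000L, patience = 5L,
                            min_delta = 0, learning_rate = 1e-3,
                            early_stopping = FALSE, seed = 1L) {
  stopifnot(batch_size > 0, max_batches > 0, min_batches >= 0,
            valid_interval > 0, valid_sample > 0, patience > 0,
            min_delta >= 0, learning_rate > 0)
  structure(list(batch_size = as.integer(batch_size),
                 max_batches = as.integer(max_batches),
                 min_batches = as.integer(min_batches),
                 valid_interval = as.integer(valid_interval),
                 valid_sample = as.integer(valid_sample),
                 patience = as.integer(patience),
                 min_delta = min_delta,
                 learning_rate = learning_rate,
                 early_stopping = early_stopping,
                 seed = as.integer(seed)),
            class = "training_config")
}

## ---- parameters -----------------------------------------------------------

# Flat named parameter list: c<k>_W1, c<k>_b1, c<k>_W2, c<k>_b2, W3, b3.
init_params <- function(specs, n_targets) {
  params <- list()
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    params[[paste0("c", k, "_W1")]] <- init_mat(sp$input_dim, sp$layer1_dim)
    params[[paste0("c", k, "_b1")]] <- init_mat(1L, sp$layer1_dim,
                                                fan_in = sp$input_dim)[1, ]
    params[[paste0("c", k, "_W2")]] <- init_mat(sp$layer1_dim, sp$layer2_dim)
    params[[paste0("c", k, "_b2")]] <- init_mat(1L, sp$layer2_dim,
                                                fan_in = sp$layer1_dim)[1, ]
  }
  h <- sum(vapply(specs, `[[`, integer(1), "layer2_dim"))
  params$W3 <- init_mat(h, n_targets)
  params$b3 <- init_mat(1L, n_targets, fan_in = h)[1, ]
  params
}

# symmetric uniform fan-in initialization
init_mat <- function(nr, nc, fan_in = nr) {
  lim <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

## ---- forward / loss / backward -------------------------------------------

#' Forward pass of the channelized network
#'
#' @param params Parameter list as built by \code{\link{rotation_training}}
#'   (or a model's \code{$params}).
#' @param x_list List of per-channel feature matrices (instances x
#'   \code{input_dim}), in channel order.
#' @return List with \code{probs} (instances x targets, in (0,1)),
#'   \code{logits}, and the activations cache used by backprop.
#' @export
forward_pass <- function(params, x_list) {
  n_ch <- length(x_list)
  a1 <- a2 <- vector("list", n_ch)
  for (k in seq_len(n_ch)) {
    W1 <- params[[paste0("c", k, "_W1")]]
    if (ncol(x_list[[k]]) != nrow(W1))
      stop(sprintf("channel %d: feature width %d does not match input dim %d",
                   k, ncol(x_list[[k]]), nrow(W1)))
    a1[[k]] <- tanh(sweep(x_list[[k]] %*% W1, 2L,
                          params[[paste0("c", k, "_b1")]], "+"))
    a2[[k]] <- tanh(sweep(a1[[k]] %*% params[[paste0("c", k, "_W2")]], 2L,
                          params[[paste0("c", k, "_b2")]], "+"))
  }
  z <- do.call(cbind, a2)
  logits <- sweep(z %*% params$W3, 2L, params$b3, "+")
  list(probs = stats::plogis(logits), logits = logits,
       cache = list(x = x_list, a1 = a1, a2 = a2, z = z))
}

#' Numerically stable sigmoid cross-entropy loss
#'
#' Elementwise \code{max(l, 0) - l * y + log(1 + exp(-|l|))} averaged over all
#' entries; algebraically equal to the logistic loss
#' \code{-y log(sigmoid(l)) - (1 - y) log(1 - sigmoid(l))} but stable for
#' large magnitude logits.
#'
#' @param logits Numeric vector or matrix of logits.
#' @param labels Binary labels, same shape.
#' @return Scalar mean loss.
#' @export
sigmoid_xent_loss <- function(logits, labels) {
  if (length(logits) != length(labels)) stop("logits/labels length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  mean(pmax(logits, 0) - logits * labels + log1p(exp(-abs(logits))))
}

# Gradients of sigmoid_xent_loss(forward_pass(params, x)$logits, y)
# with respect to every parameter.
backward_pass <- function(params, fwd, labels) {
  n_ch <- length(fwd$cache$x)
  g <- list()
  dlogits <- (fwd$probs - labels) / length(labels)
  g$W3 <- crossprod(fwd$cache$z, dlogits)
  g$b3 <- colSums(dlogits)
  dz <- dlogits %*% t(params$W3)
  col0 <- 0L
  for (k in seq_len(n_ch)) {
    a1 <- fwd$cache$a1[[k]]; a2 <- fwd$cache$a2[[k]]
    h2 <- ncol(a2)
    dz_k <- dz[, (col0 + 1L):(col0 + h2), drop = FALSE]
    col0 <- col0 + h2
    da2 <- dz_k * (1 - a2^2)
    g[[paste0("c", k, "_W2")]] <- crossprod(a1, da2)
    g[[paste0("c", k, "_b2")]] <- colSums(da2)
    da1 <- (da2 %*% t(params[[paste0("c", k, "_W2")]])) * (1 - a1^2)
    g[[paste0("c", k, "_W1")]] <- crossprod(fwd$cache$x[[k]], da1)
    g[[paste0("c", k, "_b1")]] <- colSums(da1)
  }
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## ---- early stopping -------------------------------------------------------

#' Early-stopping decision from a validation loss history
#'
#' Halts once the best loss seen so far has failed to improve by more than
#' \code{min_delta} for \code{patience} consecutive evaluations.
#'
#' @param valid_loss_history Numeric vector of train-validation losses,
#'   oldest first (nonempty).
#' @param patience Consecutive non-improving evaluations tolerated.
#' @param min_delta Required decrease below the best loss to count as
#'   improvement.
#' @return \code{"halt"} or \code{"continue"}.
#' @export
early_stopping_check <- function(valid_loss_history, patience = 5L,
                                 min_delta = 0) {
  if (length(valid_loss_history) == 0L) stop("empty loss history")
  best <- Inf
  stale <- 0L
  for (loss in valid_loss_history) {
    if (loss < best - min_delta) {
      best <- min(best, loss)
      stale <- 0L
    } else {
      best <- min(best, loss)
      stale <- stale + 1L
    }
  }
  if (stale >= patience) "halt" else "continue"
}

## ---- feature construction -------------------------------------------------

#' Per-cell feature blocks for a set of regions
#'
#' For each reference cell type k the feature block at region i is the cell's
#' binary target vector at i concatenated with the similarity vector between
#' the query tracks and the cell's tracks at i.
#'
#' @param regions Global bin indices; every region must belong to the
#'   dataset's region index.
#' @param dataset A \code{\link{build_dataset}} dataset.
#' @param query_tracks Named list (assay -> \code{\link{binned_track}}) for
#'   the query context; must cover \code{casv_assays}.
#' @param targets Model targets (default: all dataset targets).
#' @param casv_assays Assays entering the similarity vector (default: the
#'   accessibility assay).
#' @param windows A \code{\link{casv_windows}}.
#' @param casv_mode \code{"casv"} for the real similarity vector,
#'   \code{"identity"} for the constant identity vector (ablation).
#' @param cells Reference cells, in channel order (default: dataset cells).
#' @return Named list of per-cell matrices (\code{length(regions)} rows).
#' @export
build_features <- function(regions, dataset, query_tracks,
                           targets = dataset$targets,
                           casv_assays = dataset$accessibility_assay,
                           windows = casv_windows(),
                           casv_mode = c("casv", "identity"),
                           cells = dataset$cells) {
  casv_mode <- match.arg(casv_mode)
  if (!all(regions %in% dataset$region_index))
    stop("region outside the dataset region index")
  missing_a <- setdiff(casv_assays, names(query_tracks))
  if (length(missing_a))
    stop("query tracks missing assay(s): ", paste(missing_a, collapse = ", "))
  n <- length(regions)
  m <- length(windows$sizes)
  blocks <- lapply(cells, function(cl) {
    avail <- intersect(targets, cell_targets(dataset, cl))
    f <- region_label_matrix(dataset, cl, assays = avail, regions = regions)
    if (casv_mode == "identity") {
      cv <- matrix(rep(identity_casv(windows, length(casv_assays)),
                       each = n), nrow = n)
    } else {
      ref <- stats::setNames(
        lapply(casv_assays, function(a) get_track(dataset, cl, a)),
        casv_assays)
      cv <- multi_assay_casv(regions, query_tracks, ref, casv_assays, windows)
      if (n == 1L) cv <- matrix(cv, nrow = 1L)
    }
    cbind(f, cv)
  })
  stats::setNames(blocks, cells)
}

cell_targets <- function(dataset, cell) {
  assays <- vapply(dataset$tracks, `[[`, character(1), "assay")
  cells <- vapply(dataset$tracks, `[[`, character(1), "cell")
  setdiff(assays[cells == cell], dataset$accessibility_assay)
}

#' Rotation schedule of training instances
#'
#' One epoch visits every (region, label cell) pair exactly once: regions in
#' the given (possibly shuffled) order, and for each region every cell in
#' dataset order supplying the labels once.
#'
#' @param regions Global bin indices (possibly resampled by the sampler).
#' @param cells Cell identifiers in rotation order.
#' @return data.frame with columns \code{region} and \code{cell}.
#' @export
rotation_schedule <- function(regions, cells) {
  data.frame(region = rep(regions, each = length(cells)),
             cell = rep(cells, times = length(regions)),
             stringsAsFactors = FALSE)
}

## ---- training -------------------------------------------------------------

# sample training regions according to the configured imbalance strategy
sample_training_regions <- function(dataset, regions, targets, mode, ratio,
                                    seed) {
  lab <- label_any_cell(dataset, regions, targets)
  if (mode == "auto")
    mode <- if (length(targets) == 1L) "single_target" else "multi_label"
  switch(mode,
    none = regions,
    single_target = {
      pos <- regions[lab[, 1L] == 1L]
      neg <- regions[lab[, 1L] == 0L]
      undersample_single_target(pos, neg, ratio = ratio, seed = seed)
    },
    multi_label = {
      summ <- imbalance_summary(lab)
      oversample_instances(regions, lab, summ, seed = seed)
    },
    stop("unknown sampler mode: ", mode))
}

# regions x targets indicator: 1 iff any cell has a peak for the target there
label_any_cell <- function(dataset, regions, targets) {
  out <- vapply(targets, function(tg) {
    v <- integer(length(regions))
    for (cl in dataset$cells) {
      key <- paste(cl, tg, sep = "|")
      if (key %in% names(dataset$tracks))
        v <- pmax(v, dataset$tracks[[key]]$values[regions])
    }
    v
  }, integer(length(regions)))
  matrix(out, nrow = length(regions), dimnames = list(NULL, targets))
}

#' Train a multi-cell-type model by cell-type rotation
#'
#' Iterates over training regions and, for each region, rotates through the
#' reference cell types: the rotation cell supplies the labels (its ChIP-seq
#' peaks for the model targets at that region) and every cell type --
#' including the label cell itself, whose similarity vector is then the
#' identity similarity of its accessibility track with itself -- supplies its
#' feature channel. Parameters are updated by Adam on batches of
#' \code{config$batch_size} instances under the stable sigmoid cross-entropy
#' loss. Training halts at \code{config$max_batches} or, when early stopping
#' is enabled, once the train-validation loss (evaluated every
#' \code{config$valid_interval} batches on \code{config$valid_sample}
#' instances drawn from the train_valid partition) plateaus for
#' \code{config$patience} evaluations.
#'
#' @param dataset A \code{\link{build_dataset}} dataset.
#' @param targets ChIP targets to predict (default: all dataset targets).
#'   Every training cell must carry every predicted target.
#' @param cells Reference cell types (default: all dataset cells).
#' @param casv_assays Assays entering the similarity vector (default:
#'   accessibility only).
#' @param windows A \code{\link{casv_windows}}.
#' @param casv_mode \code{"casv"} (default) or \code{"identity"} for the
#'   constant-similarity ablation.
#' @param sampler \code{"auto"} (single-target undersampling for one target,
#'   multi-label oversampling otherwise), \code{"single_target"},
#'   \code{"multi_label"} or \code{"none"}.
#' @param undersample_ratio Negative:positive ratio for single-target
#'   undersampling (default 10).
#' @param config A \code{\link{training_config}}.
#' @return Object of class \code{epibind_model}: \code{params},
#'   \code{specs}, \code{cells}, \code{targets}, \code{casv} settings,
#'   \code{loss_history} (per batch), \code{valid_history}, and
#'   \code{n_batches}.
#' @export
rotation_training <- function(dataset, targets = dataset$targets,
                              cells = dataset$cells,
                              casv_assays = dataset$accessibility_assay,
                              windows = casv_windows(),
                              casv_mode = c("casv", "identity"),
                              sampler = c("auto", "single_target",
                                          "multi_label", "none"),
                              undersample_ratio = 10,
                              config = training_config()) {
  casv_mode <- match.arg(casv_mode)
  sampler <- match.arg(sampler)
  stopifnot(inherits(config, "training_config"))
  if (length(cells) < 2L) stop("need at least two reference cell types")
  for (cl in cells) {
    miss <- setdiff(targets, cell_targets(dataset, cl))
    if (length(miss))
      stop("cell ", cl, " lacks predicted target(s): ",
           paste(miss, collapse = ", "))
    for (a in casv_assays)
      get_track(dataset, cl, a)  # errors if absent
  }
  train_regions <- dataset$region_index[dataset$partition == "train"]
  if (length(train_regions) == 0L) stop("empty training partition")

  set.seed(config$seed)
  sampled <- sample_training_regions(dataset, train_regions, targets,
                                     sampler, undersample_ratio,
                                     seed = config$seed)
  if (length(sampled) == 0L) stop("sampler produced an empty instance index")

  tv_sampled <- NULL
  if (config$early_stopping) {
    tv_regions <- dataset$region_index[dataset$partition == "train_valid"]
    if (length(tv_regions) == 0L)
      stop("early stopping requires a train_valid partition")
    tv_sampled <- sample_training_regions(dataset, tv_regions, targets,
                                          sampler, undersample_ratio,
                                          seed = config$seed + 1L)
  }

  m_assays <- length(casv_assays)
  specs <- lapply(cells, function(cl)
    channel_spec(cl, intersect(targets, cell_targets(dataset, cl)),
                 casv_length = 2L * length(windows$sizes) * m_assays))
  set.seed(config$seed)
  params <- init_params(specs, length(targets))
  state <- adam_init(params)

  # feature caches over the full region index
  ridx <- dataset$region_index
  row_of <- function(bins) match(bins, ridx)
  fmats <- lapply(cells, function(cl)
    region_label_matrix(dataset, cl,
                        assays = intersect(targets, cell_targets(dataset, cl))))
  names(fmats) <- cells
  casv_cache <- new.env(parent = emptyenv())
  pair_casv <- function(qc, kc) {
    key <- paste(sort(c(qc, kc)), collapse = "||")
    if (is.null(casv_cache[[key]])) {
      qtr <- stats::setNames(lapply(casv_assays, function(a)
        get_track(dataset, qc, a)), casv_assays)
      ktr <- stats::setNames(lapply(casv_assays, function(a)
        get_track(dataset, kc, a)), casv_assays)
      cv <- multi_assay_casv(ridx, qtr, ktr, casv_assays, windows)
      casv_cache[[key]] <- matrix(cv, nrow = length(ridx))
    }
    casv_cache[[key]]
  }
  const_casv <- identity_casv(windows, m_assays)

  assemble <- function(inst_rows, inst_cells) {
    # inst_rows: row indices into ridx; inst_cells: label cell per instance
    x_list <- vector("list", length(cells))
    for (j in seq_along(cells)) {
      cj <- cells[j]
      f <- fmats[[cj]][inst_rows, , drop = FALSE]
      if (casv_mode == "identity") {
        cv <- matrix(rep(const_casv, each = length(inst_rows)),
                     nrow = length(inst_rows))
      } else {
        cv <- matrix(0, length(inst_rows), 2L * length(windows$sizes) * m_assays)
        for (k in unique(inst_cells)) {
          sel <- inst_cells == k
          cv[sel, ] <- pair_casv(k, cj)[inst_rows[sel], , drop = FALSE]
        }
      }
      x_list[[j]] <- cbind(f, cv)
    }
    y <- matrix(0L, length(inst_rows), length(targets))
    for (k in unique(inst_cells)) {
      sel <- inst_cells == k
      y[sel, ] <- fmats[[k]][inst_rows[sel], targets, drop = FALSE]
    }
    list(x = x_list, y = y)
  }

  loss_history <- numeric(0)
  valid_history <- numeric(0)
  batch <- 0L
  halted <- FALSE
  inst_rows <- integer(0); inst_cells <- character(0); cursor <- 1L
  while (batch < config$max_batches && !halted) {
    if (cursor > length(inst_rows)) {  # new epoch: reshuffle regions
      epoch_regions <- sampled[sample.int(length(sampled))]
      sched <- rotation_schedule(epoch_regions, cells)
      inst_rows <- row_of(sched$region)
      inst_cells <- sched$cell
      cursor <- 1L
    }
    take <- seq(cursor, min(cursor + config$batch_size - 1L,
                            length(inst_rows)))
    cursor <- cursor + length(take)
    ba <- assemble(inst_rows[take], inst_cells[take])
    fwd <- forward_pass(params, ba$x)
    loss_history <- c(loss_history, sigmoid_xent_loss(fwd$logits, ba$y))
    grads <- backward_pass(params, fwd, ba$y)
    upd <- adam_step(params, grads, state, lr = config$learning_rate)
    params <- upd$params; state <- upd$state
    batch <- batch + 1L

    if (config$early_stopping && batch %% config$valid_interval == 0L) {
      tv_sched <- rotation_schedule(tv_sampled, cells)
      draw <- sample.int(nrow(tv_sched),
                         min(config$valid_sample, nrow(tv_sched)))
      vb <- assemble(row_of(tv_sched$region[draw]), tv_sched$cell[draw])
      vfwd <- forward_pass(params, vb$x)
      valid_history <- c(valid_history,
                         sigmoid_xent_loss(vfwd$logits, vb$y))
      if (batch >= config$min_batches &&
          early_stopping_check(valid_history, config$patience,
                               config$min_delta) == "halt")
        halted <- TRUE
    }
  }

  structure(list(params = params, specs = specs, cells = cells,
                 targets = targets,
                 casv = list(assays = casv_assays, windows = windows,
                             mode = casv_mode),
                 accessibility_assay = dataset$accessibility_assay,
                 loss_history = loss_history,
                 valid_history = valid_history,
                 n_batches = batch, halted_early = halted,
                 config = config),
            class = "epibind_model")
}

#' @export
print.epibind_model <- function(x, ...) {
  cat(sprintf(paste0("epibind_model: %d channels, %d target(s), ",
                     "%d batches trained (final loss %.4f)\n"),
              length(x$cells), length(x$targets), x$n_batches,
              utils::tail(x$loss_history, 1)))
  invisible(x)
}

## ---- prediction -----------------------------------------------------------

#' Predict peak probabilities for a query context
#'
#' Runs the forward pass at the requested regions using the query context's
#' accessibility (and any further similarity assays the model was configured
#' with). Regions outside the dataset's region index -- bins where no
#' reference cell type carries any peak -- are predicted as exactly 0.
#'
#' @param object An \code{epibind_model}.
#' @param dataset The \code{\link{build_dataset}} dataset the model was
#'   trained on (supplies the reference feature tracks).
#' @param query_tracks Named list (assay -> \code{\link{binned_track}})
#'   characterizing the query; must cover the model's similarity assays and
#'   be binned on the dataset grid.
#' @param regions Global bin indices to predict at (default: the dataset's
#'   test partition).
#' @param ... Unused.
#' @return Numeric matrix \code{length(regions)} x targets of probabilities
#'   (column names are the targets).
#' @export
predict.epibind_model <- function(object, dataset, query_tracks,
                                  regions = dataset$region_index[
                                    dataset$partition == "test"], ...) {
  for (a in object$casv$assays) {
    tr <- query_tracks[[a]]
    if (is.null(tr)) stop("query tracks missing assay: ", a)
    if (!identical(tr$grid, dataset$grid))
      stop("query track not binned on the dataset grid")
  }
  if (any(regions < 1L | regions > dataset$grid$total_bins))
    stop("region off the grid")
  out <- matrix(0, length(regions), length(object$targets),
                dimnames = list(NULL, object$targets))
  inside <- regions %in% dataset$region_index
  if (any(inside)) {
    x_list <- build_features(regions[inside], dataset, query_tracks,
                             targets = object$targets,
                             casv_assays = object$casv$assays,
                             windows = object$casv$windows,
                             casv_mode = object$casv$mode,
                             cells = object$cells)
    out[inside, ] <- forward_pass(object$params, unname(x_list))$probs
  }
  out
}

#' Tabulate predictions as region/target/probability rows
#'
#' @param model An \code{epibind_model}.
#' @param dataset The training dataset.
#' @param probs Matrix from \code{\link{predict.epibind_model}}.
#' @param regions The global bin indices the rows of \code{probs} refer to.
#' @return data.frame with chrom, start, end, target, prob -- suitable for
#'   writing as a bedGraph-style TSV.
#' @export
predictions_to_df <- function(model, dataset, probs, regions) {
  co <- bin_coords(dataset$grid, regions)
  do.call(rbind, lapply(seq_along(model$targets), function(j) {
    data.frame(co, target = model$targets[j], prob = probs[, j],
               stringsAsFactors = FALSE)
  }))
}
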