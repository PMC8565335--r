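test_that("channel dimensions follow the halve/quarter rule", {
  sp <- channel_spec("K562", "CTCF", casv_length = 8)
  expect_equal(sp$input_dim, 9L)
  expect_equal(c(sp$layer1_dim, sp$layer2_dim), c(4L, 2L))
  sp2 <- channel_spec("K562", paste0("t", 1:250), casv_length = 8)
  expect_equal(sp2$input_dim, 258L)
  expect_equal(c(sp2$layer1_dim, sp2$layer2_dim), c(129L, 64L))
  # hidden dims never collapse to zero
  sp3 <- channel_spec("c", character(0), casv_length = 2)
  expect_gte(sp3$layer2_dim, 1L)
})

make_tiny_net <- function(seed = 1, dims = c(5L, 9L), n_targets = 2L) {
  set.seed(seed)
  # exact input dims: dims[k] pseudo-targets, no similarity block
  specs <- lapply(seq_along(dims), function(k)
    channel_spec(paste0("c", k), paste0("t", seq_len(dims[k])),
                 casv_length = 0))
  params <- epibind:::init_params(specs, n_targets)
  list(specs = specs, params = params)
}

test_that("forward pass has sigmoid range and detects width mismatches", {
  net <- make_tiny_net()
  x <- list(matrix(stats::runif(4 * 5), 4, 5), matrix(stats::runif(4 * 9), 4, 9))
  out <- forward_pass(net$params, x)
  expect_true(all(out$probs > 0 & out$probs < 1))
  expect_equal(dim(out$probs), c(4L, 2L))
  # all-zero parameters give sigmoid(0) = 0.5 everywhere
  zero_params <- lapply(net$params, function(p) p * 0)
  expect_true(all(forward_pass(zero_params, x)$probs == 0.5))
  expect_error(forward_pass(net$params, rev(x)), "does not match")
})

test_that("stable cross-entropy equals the textbook logistic loss", {
  expect_equal(sigmoid_xent_loss(0, 0), log(2))
  expect_equal(sigmoid_xent_loss(0, 1), log(2))
  expect_equal(sigmoid_xent_loss(2, 1), log(1 + exp(-2)))
  set.seed(12)
  l <- stats::runif(1e5, -20, 20)
  y <- stats::rbinom(1e5, 1, 0.5)
  ours <- pmax(l, 0) - l * y + log1p(exp(-abs(l)))
  textbook <- -y * log(stats::plogis(l)) - (1 - y) * log(stats::plogis(-l))
  expect_lt(max(abs(ours - textbook)), 1e-9)
  expect_true(all(ours >= 0))
  # loss only vanishes in the matched large-logit limit
  expect_lt(sigmoid_xent_loss(50, 1), 1e-20)
  expect_gt(sigmoid_xent_loss(50, 0), 1)
})

test_that("analytic gradients match central finite differences", {
  net <- make_tiny_net(seed = 4)
  set.seed(5)
  x <- list(matrix(stats::runif(6 * 5), 6, 5), matrix(stats::runif(6 * 9), 6, 9))
  y <- matrix(stats::rbinom(12, 1, 0.5), 6, 2)
  loss_at <- function(params)
    sigmoid_xent_loss(forward_pass(params, x)$logits, y)
  grads <- epibind:::backward_pass(net$params, forward_pass(net$params, x), y)
  eps <- 1e-6
  for (nm in names(net$params)) {
    p <- net$params[[nm]]
    for (j in seq_along(p)) {
      up <- net$params; up[[nm]][j] <- p[j] + eps
      dn <- net$params; dn[[nm]][j] <- p[j] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_lt(abs(num - grads[[nm]][j]), 1e-5)
    }
  }
})

test_that("rotation schedule visits every (region, label cell) pair once", {
  sched <- rotation_schedule(c(10L, 20L), c("k1", "k2"))
  expect_equal(nrow(sched), 4L)
  # one region, two cells: exactly two instances
  expect_equal(nrow(rotation_schedule(5L, c("k1", "k2"))), 2L)
  sched <- rotation_schedule(sample(1:50), paste0("k", 1:3))
  key <- paste(sched$region, sched$cell)
  expect_equal(anyDuplicated(key), 0L)
  expect_equal(nrow(sched), 150L)
})

test_that("training is deterministic and learns on structured data", {
  ds <- tiny_dataset(seed = 42)
  cfg <- training_config(max_batches = 150, min_batches = 0, seed = 11)
  m1 <- rotation_training(ds, config = cfg)
  m2 <- rotation_training(ds, config = cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_equal(m1$n_batches, 150L)
  # accessibility drives the peaks here, so the loss must come down
  expect_lt(mean(utils::tail(m1$loss_history, 10)),
            mean(utils::head(m1$loss_history, 10)))
})

test_that("early stopping halts after patience non-improving evaluations", {
  expect_equal(early_stopping_check(c(1.0, 0.9, 0.8), patience = 5), "continue")
  expect_equal(early_stopping_check(rep(1.0, 6), patience = 5, min_delta = 0),
               "halt")
  expect_equal(early_stopping_check(rep(1.0, 5), patience = 5), "continue")
  # an improvement below min_delta does not reset the counter
  expect_equal(early_stopping_check(c(1.0, 0.7), patience = 1,
                                    min_delta = 0.5), "halt")
  expect_equal(early_stopping_check(c(1.0, 0.4), patience = 1,
                                    min_delta = 0.5), "continue")
  expect_error(early_stopping_check(numeric(0)), "empty")
})

test_that("rotation training integrates early stopping on the train_valid set", {
  ds <- tiny_dataset(seed = 42)
  cfg <- training_config(max_batches = 400, min_batches = 0,
                         valid_interval = 10, valid_sample = 50,
                         patience = 3, min_delta = 1, early_stopping = TRUE,
                         seed = 2)
  m <- rotation_training(ds, config = cfg)
  expect_true(m$halted_early)
  # first evaluation improves on Inf; then at most `patience` stale ones
  expect_lte(m$n_batches, (1 + cfg$patience) * cfg$valid_interval)
  expect_length(m$valid_history, m$n_batches / cfg$valid_interval)
  # without a train_valid partition early stopping must refuse to run
  ds2 <- tiny_dataset(seed = 42)
  ds2$partition[ds2$partition == "train_valid"] <- "train"
  expect_error(rotation_training(ds2, config = cfg), "train_valid")
})

test_that("build_features concatenates peaks with the similarity vector", {
  g <- bin_grid(c(chr1 = 40000))  # 200 bins
  zero <- integer(200)
  accA <- zero; accA[1] <- 1L
  accB <- zero; accB[100] <- 1L
  tgA <- zero; tgA[1] <- 1L
  tgB <- zero; tgB[100] <- 1L
  ds <- build_dataset(list(binned_track("A", "accessibility", accA, g),
                           binned_track("A", "target1", tgA, g),
                           binned_track("B", "accessibility", accB, g),
                           binned_track("B", "target1", tgB, g)),
                      g, split = split_config(valid = character(0),
                                              test = character(0),
                                              train_valid = NULL))
  expect_equal(ds$region_index, c(1L, 100L))
  query <- list(accessibility = get_track(ds, "A", "accessibility"))
  fb <- build_features(100L, ds, query)
  expect_named(fb, c("A", "B"))
  expect_equal(ncol(fb$A), 9L)  # 1 target + 8-dim similarity
  # query == cell A, and nothing is accessible near bin 100 in either:
  expect_equal(drop(fb$A), c(0, 0, 0, 0, 0, 1, 1, 1, 1),
               ignore_attr = TRUE)
  expect_error(build_features(50L, ds, query), "region index")
  expect_error(build_features(100L, ds, list()), "missing assay")
})

test_that("prediction is zero outside the region index and in [0,1] inside", {
  ds <- tiny_dataset(seed = 8)
  m <- rotation_training(ds, config = training_config(max_batches = 60,
                                                      min_batches = 0,
                                                      seed = 1))
  query <- list(accessibility = get_track(ds, ds$cells[1], "accessibility"))
  outside <- setdiff(seq_len(ds$grid$total_bins), ds$region_index)[1:5]
  inside <- ds$region_index[1:5]
  p <- predict(m, ds, query, regions = c(outside, inside))
  expect_true(all(p[1:5, ] == 0))
  expect_true(all(p[6:10, ] > 0 & p[6:10, ] < 1))
  expect_error(predict(m, ds, query, regions = 10^9), "off the grid")
  df <- predictions_to_df(m, ds, p, c(outside, inside))
  expect_equal(nrow(df), 10L)
  expect_named(df, c("chrom", "start", "end", "target", "prob"))
})

test_that("a model archive round-trips to identical predictions", {
  ds <- tiny_dataset(seed = 8)
  m <- rotation_training(ds, config = training_config(max_batches = 40,
                                                      min_batches = 0,
                                                      seed = 6))
  path <- withr::local_tempfile(fileext = ".json.gz")
  save_model(m, path)
  m2 <- load_model(path)
  query <- list(accessibility = get_track(ds, ds$cells[2], "accessibility"))
  regions <- ds$region_index[ds$partition == "test"]
  expect_equal(predict(m2, ds, query, regions = regions),
               predict(m, ds, query, regions = regions))
  expect_equal(m2$casv$windows$sizes, m$casv$windows$sizes)
})
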