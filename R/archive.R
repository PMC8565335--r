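#' Save a trained model to a JSON archive
#'
#' Self-describing archive: weights, channel specifications, similarity
#' configuration and target/assay order, written as (optionally gzipped)
#' JSON with full numeric precision.
#'
#' @param model An \code{epibind_model}.
#' @param path Output path (a \code{.gz} suffix gzips the file).
#' @return \code{path}, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "epibind_model"))
  arch <- list(
    format = "epibind_model",
    version = 1L,
    cells = model$cells,
    targets = model$targets,
    accessibility_assay = model$accessibility_assay,
    casv = list(assays = model$casv$assays,
                ring_bins = model$casv$windows$sizes,
                mode = model$casv$mode),
    specs = lapply(model$specs, function(sp)
      list(cell = sp$cell, targets_available = sp$targets_available,
           casv_length = sp$casv_length)),
    params = lapply(model$params, function(p)
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = NULL, data = as.numeric(p))),
    n_batches = model$n_batches,
    loss_history = model$loss_history,
    valid_history = model$valid_history)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(arch, auto_unbox = TRUE, digits = NA,
                              null = "null"), con)
  invisible(path)
}

#' Load a model archive written by \code{\link{save_model}}
#'
#' @param path Archive path.
#' @return An \code{epibind_model} (without a training config).
#' @export
load_model <- function(path) {
  arch <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(arch$format, "epibind_model"))
    stop("not an epibind model archive: ", path)
  params <- lapply(arch$params, function(p) {
    data <- as.numeric(unlist(p$data))
    if (is.null(p$dim)) data
    else matrix(data, unlist(p$dim)[1], unlist(p$dim)[2])
  })
  specs <- lapply(arch$specs, function(sp)
    channel_spec(sp$cell, unlist(sp$targets_available),
                 casv_length = sp$casv_length))
  structure(list(
    params = params, specs = specs,
    cells = unlist(arch$cells), targets = unlist(arch$targets),
    casv = list(assays = unlist(arch$casv$assays),
                windows = casv_windows(unlist(arch$casv$ring_bins)),
                mode = arch$casv$mode),
    accessibility_assay = arch$accessibility_assay,
    loss_history = as.numeric(unlist(arch$loss_history)),
    valid_history = as.numeric(unlist(arch$valid_history)),
    n_batches = arch$n_batches, halted_early = NA,
    config = NULL), class = "epibind_model")
}
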