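#' Write one raw-signal experiment to disk
#'
#' One file per recording session: `signal` (channels x samples x 15
#' array), `labels` (15 ints), `subject_id`, `experiment_id`, `fs`,
#' `channels`. Serialized as RDS with this fixed layout; the loader for
#' externally pre-extracted arrays accepts the same layout.
#'
#' @param batch one experiment batch from [generate_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_experiment <- function(batch, path) {
  n <- ncol(batch$trials[[1]]$signal)
  sig <- array(0, dim = c(nrow(batch$trials[[1]]$signal), n, 15L))
  for (i in 1:15) sig[, , i] <- batch$trials[[i]]$signal
  saveRDS(list(
    signal = sig,
    labels = as.integer(batch$labels),
    subject_id = batch$subject_id,
    experiment_id = batch$experiment_id,
    fs = batch$trials[[1]]$sampling_rate,
    channels = rownames(batch$trials[[1]]$signal)
  ), path)
  invisible(path)
}

#' Read one raw-signal experiment written by [write_experiment()]
#'
#' @param path file path.
#' @return an experiment batch (same structure as [generate_dataset()]
#'   elements, without drift metadata).
#' @export
read_experiment <- function(path) {
  obj <- readRDS(path)
  for (f in c("signal", "labels", "subject_id", "experiment_id", "fs"))
    if (is.null(obj[[f]])) stop("experiment file missing field: ", f)
  if (length(obj$labels) != 15) stop("labels must hold 15 trial labels")
  trials <- lapply(1:15, function(i) {
    sig <- obj$signal[, , i]
    rownames(sig) <- obj$channels
    structure(list(signal = sig, label = obj$labels[i],
                   subject_id = obj$subject_id,
                   experiment_id = obj$experiment_id,
                   trial_index = i - 1L, sampling_rate = obj$fs),
              class = "raw_trial")
  })
  list(subject_id = obj$subject_id, experiment_id = obj$experiment_id,
       trials = trials, labels = obj$labels, drift = NULL)
}

#' Write a feature dataset, one file per experiment
#'
#' Each file holds `tensors` (58 x 5 x 180 x 15 array), `labels`,
#' `subject_id`, `experiment_id`, `feature_type`, `band_edges`, `lds`.
#'
#' @param fds feature dataset.
#' @param dir output directory (created if needed).
#' @return vector of file paths, invisibly.
#' @export
write_feature_dataset <- function(fds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (e in fds) {
    arr <- array(unlist(e$tensors, use.names = FALSE), dim = c(58L, 5L, 180L, 15L))
    path <- file.path(dir, paste0(experiment_key(e$subject_id, e$experiment_id),
                                  "_features.rds"))
    saveRDS(list(
      tensors = arr, labels = as.integer(e$labels),
      subject_id = e$subject_id, experiment_id = e$experiment_id,
      feature_type = attr(e$tensors[[1]], "feature_type"),
      band_edges = band_scheme(),
      lds = isTRUE(attr(e$tensors[[1]], "lds"))
    ), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Load pre-extracted feature tensors
#'
#' Accepts a directory of per-experiment files in the
#' [write_feature_dataset()] layout (also the layout for externally
#' pre-extracted arrays). Tensors are validated: 58 channels, 5 bands,
#' 180 epochs, 15 trials, labels present.
#'
#' @param path directory containing `*_features.rds` files, or a single
#'   file.
#' @return a feature dataset usable by every downstream stage.
#' @export
load_external_features <- function(path) {
  files <- if (dir.exists(path)) {
    sort(list.files(path, pattern = "_features\\.rds$", full.names = TRUE))
  } else if (file.exists(path)) path else character(0)
  if (length(files) == 0) stop("no feature files found under ", path)
  out <- lapply(files, function(f) {
    obj <- readRDS(f)
    if (is.null(obj$labels)) stop(f, ": missing labels")
    d <- dim(obj$tensors)
    if (is.null(d) || length(d) != 4)
      stop(f, ": tensors must be a 4-d array (channels, bands, epochs, trials)")
    if (d[1] != 58)
      stop(f, ": expected 58 channels, found ", d[1])
    if (d[2] != 5) stop(f, ": expected 5 bands, found ", d[2])
    if (d[3] != 180) stop(f, ": expected 180 epochs, found ", d[3])
    if (d[4] != 15 || length(obj$labels) != 15)
      stop(f, ": expected 15 trials with 15 labels")
    tensors <- lapply(1:15, function(i) {
      t <- obj$tensors[, , , i]
      dimnames(t) <- list(retained_channels(), band_scheme()$band, NULL)
      attr(t, "feature_type") <- obj$feature_type
      attr(t, "lds") <- obj$lds
      attr(t, "experiment_key") <- experiment_key(obj$subject_id,
                                                  obj$experiment_id)
      t
    })
    list(subject_id = obj$subject_id, experiment_id = obj$experiment_id,
         labels = obj$labels, drift = NULL, tensors = tensors)
  })
  attr(out, "feature_type") <- attr(out[[1]]$tensors[[1]], "feature_type")
  out
}
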