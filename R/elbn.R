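#' Fit experiment-level batch normalization statistics
#'
#' Computes the per-(channel, band) minimum and maximum feature value over
#' the 15 trials of one recording session. With pooling `"all_windows"`
#' (default) the extrema are taken over all 15 x N window values of the
#' session; with `"per_window_index"` extrema are computed separately at
#' each window position (the two coincide at N = 1, the only case the
#' normalization's narrative description pins down).
#'
#' @param tensors list of exactly 15 TW feature arrays (58, 5, N) from one
#'   session, all sharing shape and `experiment_key`.
#' @param pooling `"all_windows"` or `"per_window_index"`.
#' @return an `elbn_stats` list with `fmin`, `fmax` (58 x 5 matrices, or
#'   58 x 5 x N arrays for per-window pooling), `pooling`,
#'   `experiment_key`.
#' @export
fit_elbn <- function(tensors, pooling = c("all_windows", "per_window_index")) {
  pooling <- match.arg(pooling)
  if (length(tensors) != 15)
    stop("ELBN is fitted on exactly 15 trials of one session; got ",
         length(tensors))
  d <- dim(tensors[[1]])
  keys <- unique(vapply(tensors, function(t) {
    k <- attr(t, "experiment_key"); if (is.null(k)) NA_character_ else k
  }, character(1)))
  if (length(keys) != 1)
    stop("tensors come from more than one session: ", paste(keys, collapse = ", "))
  for (t in tensors)
    if (!identical(dim(t), d)) stop("tensor shape mismatch within session")
  stacked <- array(unlist(tensors, use.names = FALSE), dim = c(d, 15L))
  if (pooling == "all_windows") {
    flat <- matrix(stacked, nrow = d[1] * d[2])   # cells x (N*15)
    fmin <- matrix(apply(flat, 1, min), d[1], d[2])
    fmax <- matrix(apply(flat, 1, max), d[1], d[2])
  } else {
    fmin <- apply(stacked, c(1, 2, 3), min)
    fmax <- apply(stacked, c(1, 2, 3), max)
  }
  structure(list(fmin = fmin, fmax = fmax, pooling = pooling,
                 experiment_key = keys),
            class = "elbn_stats")
}

#' Apply experiment-level batch normalization
#'
#' Elementwise (F - F_min) / (F_max - F_min) with the session extrema from
#' [fit_elbn()]; where F_max = F_min the output is 0 (degenerate range).
#' The stats must come from the tensor's own session: the normalization is
#' strictly within-experiment.
#'
#' @param tensor TW feature array (58, 5, N).
#' @param stats an `elbn_stats` fitted on the same session.
#' @return normalized array, same dim and attributes.
#' @export
apply_elbn <- function(tensor, stats) {
  if (!inherits(stats, "elbn_stats")) stop("stats must come from fit_elbn()")
  key <- attr(tensor, "experiment_key")
  if (!is.null(key) && !is.na(stats$experiment_key) &&
      !identical(key, stats$experiment_key))
    stop("ELBN is within-experiment only: tensor is from ", key,
         " but stats were fitted on ", stats$experiment_key)
  d <- dim(tensor)
  n_w <- d[3]
  if (stats$pooling == "all_windows") {
    fmin <- array(rep(stats$fmin, n_w), dim = d)
    fmax <- array(rep(stats$fmax, n_w), dim = d)
  } else {
    if (!identical(dim(stats$fmin), d))
      stop("per-window ELBN stats were fitted at a different window count")
    fmin <- stats$fmin
    fmax <- stats$fmax
  }
  rng <- fmax - fmin
  out <- (tensor - fmin) / rng
  out[rng == 0] <- 0
  attributes(out) <- attributes(tensor)
  attr(out, "elbn") <- TRUE
  out
}

# Fit-and-apply over one session's tensors; returns the normalized list.
elbn_normalize_session <- function(tensors,
                                   pooling = c("all_windows", "per_window_index")) {
  stats <- fit_elbn(tensors, pooling = match.arg(pooling))
  lapply(tensors, apply_elbn, stats = stats)
}
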