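#' The eleven time-window lengths and their per-trial feature counts
#'
#' Each 180-epoch trial is collapsed into N = 180 / tw_length windows by
#' averaging; the per-trial feature format is then 58 x 5 x N.
#'
#' @return data.frame with columns `tw_length` (s), `n_windows`,
#'   `epochs_per_window`, ordered from 180 s down to 1 s.
#' @export
tw_table <- function() {
  tw <- c(180, 90, 60, 30, 20, 10, 5, 4, 3, 2, 1)
  data.frame(
    tw_length = tw,
    n_windows = as.integer(180 %/% tw),
    epochs_per_window = tw
  )
}

#' Aggregate an epoch feature tensor into time windows
#'
#' Window j holds the arithmetic mean of epochs ((j-1)*L, j*L] per channel
#' and band. Only the eleven lengths dividing 180 are accepted.
#'
#' @param tensor (58, 5, 180) epoch feature tensor.
#' @param tw_length window length in seconds, one of
#'   180, 90, 60, 30, 20, 10, 5, 4, 3, 2, 1.
#' @return array of dim (58, 5, N), N = 180 / tw_length, with attributes
#'   carried over plus `tw_length`.
#' @export
aggregate_tw <- function(tensor, tw_length) {
  d <- dim(tensor)
  if (length(d) != 3 || d[3] %% 1 != 0)
    stop("tensor must be a (channels, bands, epochs) array")
  if (!(tw_length %in% tw_table()$tw_length))
    stop("tw_length must be one of ", paste(tw_table()$tw_length, collapse = ", "))
  L <- as.integer(tw_length)
  n_ep <- d[3]
  if (n_ep %% L != 0)
    stop("tw_length ", L, " does not divide the epoch count ", n_ep)
  n_w <- n_ep %/% L
  # mean over each block of L epochs: reshape to (cells, L, N) and average
  flat <- matrix(tensor, nrow = d[1] * d[2])
  out <- array(0, dim = c(d[1], d[2], n_w), dimnames = dimnames(tensor))
  for (j in seq_len(n_w)) {
    cols <- ((j - 1) * L + 1):(j * L)
    out[, , j] <- if (L == 1) flat[, cols] else rowMeans(flat[, cols, drop = FALSE])
  }
  for (a in c("feature_type", "lds", "experiment_key"))
    attr(out, a) <- attr(tensor, a)
  attr(out, "tw_length") <- tw_length
  out
}
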