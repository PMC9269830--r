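#' Canonical EEG frequency bands
#'
#' The five-band scheme used throughout the pipeline: delta (1-3 Hz),
#' theta (4-7 Hz), alpha (8-13 Hz), beta (14-30 Hz), gamma (31-50 Hz).
#' Band power is integrated over 1-Hz periodogram bins whose centre
#' frequency lies in `[low, high]` inclusive.
#'
#' @return data.frame with columns `band`, `low`, `high` (Hz), ordered by
#'   increasing frequency.
#' @export
band_scheme <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    low  = c(1, 4, 8, 14, 31),
    high = c(3, 7, 13, 30, 50),
    stringsAsFactors = FALSE
  )
}

#' The 62-channel montage of the SEED recordings
#'
#' Channel names in recording order (10-20 system extended).
#'
#' @return character vector of length 62.
#' @export
seed_channel_names <- function() {
  c("FP1", "FPZ", "FP2", "AF3", "AF4",
    "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8",
    "CB1", "O1", "OZ", "O2", "CB2")
}

#' Channels excluded from feature extraction
#'
#' Four channels are dropped before feature extraction, leaving 58.
#'
#' @return character vector of the excluded channel names.
#' @export
excluded_channels <- function() c("PO5", "PO6", "CB1", "CB2")

#' The 58 retained channel names
#'
#' @return character vector of length 58, in montage order.
#' @export
retained_channels <- function() {
  setdiff(seed_channel_names(), excluded_channels())
}

#' Apply the 58-channel selection to a signal matrix
#'
#' Matches the exclusions by channel name (rownames); errors if any
#' expected channel name is absent.
#'
#' @param signal channels x samples matrix with channel names as rownames.
#' @return the 58 x samples matrix of retained channels, montage order.
#' @export
select_channels <- function(signal) {
  if (is.null(rownames(signal)))
    stop("signal must carry channel names as rownames")
  keep <- retained_channels()
  missing <- setdiff(keep, rownames(signal))
  if (length(missing) > 0)
    stop("channels absent from signal: ", paste(missing, collapse = ", "))
  signal[keep, , drop = FALSE]
}
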