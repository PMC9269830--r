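#' Segment a trial into 180 one-second epochs
#'
#' Channel selection (58 of 62) is applied first; the trial is then cut
#' into 180 consecutive non-overlapping 1-s windows starting at sample 1,
#' epoch k covering samples ((k-1)*fs, k*fs]. Surplus samples beyond 180 s
#' are discarded; trials shorter than 180 s are an error.
#'
#' @param trial a `raw_trial` (see [generate_trial()]).
#' @return 58 x fs x 180 array (channels x samples x epochs).
#' @export
segment_epochs <- function(trial) {
  fs <- trial$sampling_rate
  sig <- select_channels(trial$signal)
  need <- 180L * fs
  if (ncol(sig) < need)
    stop("trial shorter than 180 s: has ", ncol(sig), " samples, needs ", need)
  arr <- array(sig[, seq_len(need)], dim = c(58L, fs, 180L))
  dimnames(arr) <- list(retained_channels(), NULL, NULL)
  arr
}

# Hann window of length n (periodic convention is immaterial here;
# symmetric form used).
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# One-sided Hann periodogram of a 1-s epoch, normalised so the sum over
# all bins equals the window-weighted signal power sum(w^2 x^2)/sum(w^2).
# Rows of `x` are channels. Returns bins x channels matrix plus bin centre
# frequencies; the epoch mean is removed per channel first.
epoch_periodogram <- function(x, fs) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  w <- hann_window(n)
  xc <- sweep(x, 1, rowMeans(x))
  X <- stats::mvfft(t(xc * rep(w, each = nrow(x))))
  nh <- floor(n / 2)
  pxx <- (Mod(X[1:(nh + 1), , drop = FALSE])^2) / (n * sum(w^2))
  mult <- rep(2, nh + 1)
  mult[1] <- 1
  if (n %% 2 == 0) mult[nh + 1] <- 1
  pxx <- pxx * mult
  list(freq = (0:nh) * fs / n, power = pxx)
}

#' Band power of a single epoch
#'
#' Integral of the one-sided Hann-window periodogram over `[low, high]` Hz,
#' summing the bins whose centre frequency lies in the band (boundaries
#' inclusive). At 200 Hz and 1-s epochs the bins sit at integer
#' frequencies, so the integer band edges map cleanly onto bins.
#'
#' @param epoch_signal numeric vector (one channel, one epoch).
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz.
#' @return nonnegative scalar (power units).
#' @export
epoch_band_power <- function(epoch_signal, fs, low, high) {
  if (!all(is.finite(epoch_signal))) stop("non-finite values in epoch signal")
  pg <- epoch_periodogram(epoch_signal, fs)
  sum(pg$power[pg$freq >= low & pg$freq <= high, 1])
}

# Differential entropy of a Gaussian with variance equal to the band
# power: DE = 0.5 * ln(2*pi*e*P), in nats. Non-positive powers are clipped
# to a machine-epsilon-scale floor with a warning.
de_from_power <- function(p, floor = .Machine$double.eps) {
  bad <- p <= 0
  if (any(bad)) {
    warning(sum(bad), " nonpositive band power value(s) clipped to ", floor,
            " before the DE log")
    p[bad] <- floor
  }
  0.5 * log(2 * pi * exp(1) * p)
}

#' Differential entropy of one epoch in one band
#'
#' @inheritParams epoch_band_power
#' @return DE in nats.
#' @export
epoch_de <- function(epoch_signal, fs, low, high) {
  de_from_power(epoch_band_power(epoch_signal, fs, low, high))
}

#' Fixed-interval LDS smoothing of a feature sequence
#'
#' Kalman filter plus Rauch-Tung-Striebel smoother for the random-walk
#' state-space model x_t = x_{t-1} + w_t, y_t = x_t + v_t with identity
#' observation. Only the process/observation noise ratio q/r matters;
#' the observation variance is set to the sample variance of the sequence,
#' the initial state to the first observation, and the initial state
#' variance to the sample variance. Constant sequences pass through
#' unchanged.
#'
#' @param y numeric vector (one channel/band feature series over epochs).
#' @param qr_ratio process-to-observation noise ratio q/r (default 0.01;
#'   larger means less smoothing, with the identity as the limit).
#' @return smoothed vector, same length.
#' @export
lds_smooth <- function(y, qr_ratio = 0.01) {
  if (!all(is.finite(y))) stop("non-finite values in sequence")
  n <- length(y)
  v <- stats::var(y)
  if (n < 2 || !is.finite(v) || v == 0) return(y)
  r <- v
  q <- qr_ratio * r
  xf <- numeric(n); pf <- numeric(n)   # filtered
  xp <- numeric(n); pp <- numeric(n)   # one-step predictions
  xf[1] <- y[1]; pf[1] <- v
  xp[1] <- xf[1]; pp[1] <- pf[1]
  for (t in 2:n) {
    xp[t] <- xf[t - 1]
    pp[t] <- pf[t - 1] + q
    k <- pp[t] / (pp[t] + r)
    xf[t] <- xp[t] + k * (y[t] - xp[t])
    pf[t] <- (1 - k) * pp[t]
  }
  xs <- numeric(n)
  xs[n] <- xf[n]
  for (t in (n - 1):1) {
    j <- pf[t] / (pf[t] + q)
    xs[t] <- xf[t] + j * (xs[t + 1] - xf[t])
  }
  xs
}

#' Extract the epoch feature tensor of one trial
#'
#' Composes channel selection, 1-s epoch segmentation, per-epoch band
#' power (and optionally its differential-entropy transform), and optional
#' LDS smoothing along the epoch axis, yielding the (58, 5, 180) tensor.
#'
#' @param trial a `raw_trial`.
#' @param feature_type `"psd"` or `"de"`.
#' @param lds logical; smooth each (channel, band) series across epochs.
#' @param lds_qr q/r ratio for [lds_smooth()].
#' @return array of dim (58, 5, 180) with channel/band dimnames and
#'   attributes `feature_type`, `lds`, `experiment_key`.
#' @export
extract_features <- function(trial, feature_type = c("psd", "de"),
                             lds = FALSE, lds_qr = 0.01) {
  feature_type <- match.arg(feature_type)
  ep <- segment_epochs(trial)
  fs <- trial$sampling_rate
  bands <- band_scheme()
  tens <- array(0, dim = c(58L, 5L, 180L),
                dimnames = list(retained_channels(), bands$band, NULL))
  for (k in 1:180) {
    pg <- epoch_periodogram(ep[, , k], fs)
    for (b in 1:5) {
      sel <- pg$freq >= bands$low[b] & pg$freq <= bands$high[b]
      tens[, b, k] <- colSums(pg$power[sel, , drop = FALSE])
    }
  }
  if (feature_type == "de") tens <- de_from_power(tens)
  if (lds) {
    for (ch in 1:58) for (b in 1:5)
      tens[ch, b, ] <- lds_smooth(tens[ch, b, ], qr_ratio = lds_qr)
  }
  attr(tens, "feature_type") <- feature_type
  attr(tens, "lds") <- lds
  attr(tens, "experiment_key") <- experiment_key(trial$subject_id,
                                                 trial$experiment_id)
  tens
}

#' Extract feature tensors for every trial of a raw-signal dataset
#'
#' @param dataset output of [generate_dataset()].
#' @inheritParams extract_features
#' @return a feature dataset with the same structure as
#'   [simulate_feature_dataset()] output.
#' @export
extract_feature_dataset <- function(dataset, feature_type = c("psd", "de"),
                                    lds = FALSE, lds_qr = 0.01) {
  feature_type <- match.arg(feature_type)
  out <- lapply(dataset, function(batch) {
    list(
      subject_id = batch$subject_id,
      experiment_id = batch$experiment_id,
      labels = batch$labels,
      drift = batch$drift,
      tensors = lapply(batch$trials, extract_features,
                       feature_type = feature_type, lds = lds, lds_qr = lds_qr)
    )
  })
  attr(out, "config") <- attr(dataset, "config")
  attr(out, "feature_type") <- feature_type
  out
}
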