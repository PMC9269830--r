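#' Fixed emotion presentation order of one 15-trial session
#'
#' Every recording session presents the same 15 film clips, whose target
#' emotions follow a fixed order with 5 trials per class
#' (1 = positive, 0 = neutral, -1 = negative).
#'
#' @return integer vector of length 15.
#' @export
emotion_order <- function() {
  c(1L, 0L, -1L, -1L, 0L, 1L, -1L, 0L, 1L, 1L, 0L, -1L, 0L, 1L, -1L)
}

#' Default class-conditional band-power effects
#'
#' Log-power offsets per emotion class and band used by the synthetic
#' generator. The public dataset the design emulates publishes no effect
#' sizes, so these are free parameters chosen to give a distinct spectral
#' signature per class at moderate separability: the positive class raises
#' alpha and gamma power, the negative class raises theta and beta power,
#' the neutral class is the baseline.
#'
#' @param scale multiplier on the default offsets (0 removes all class
#'   structure; larger values increase separability).
#' @return 3 x 5 numeric matrix, rownames `c("-1","0","1")`, colnames the
#'   five bands; entries are log-power offsets (dimensionless).
#' @export
default_class_effects <- function(scale = 1) {
  m <- rbind(
    "-1" = c(delta = 0,   theta = 0.5, alpha = 0,   beta = 0.5, gamma = 0),
    "0"  = c(delta = 0,   theta = 0,   alpha = 0,   beta = 0,   gamma = 0),
    "1"  = c(delta = 0,   theta = 0,   alpha = 0.5, beta = 0,   gamma = 0.5)
  )
  m * scale
}

#' Configuration of the synthetic EEG generator
#'
#' Defaults mirror the emulated study: 15 subjects, 3 sessions each,
#' 15 trials per session, 62 channels at 200 Hz, 180-s trials. Drift is a
#' per-session multiplicative gain (log-normal) plus additive offset
#' (normal) applied in the band-power domain, shared by all 15 trials of a
#' session -- the structure experiment-level batch normalization targets.
#'
#' @param n_subjects number of subjects.
#' @param n_experiments_per_subject sessions per subject.
#' @param sampling_rate Hz; must be at least twice the gamma upper edge.
#' @param trial_duration seconds per trial.
#' @param n_channels number of recorded channels (62; the montage names
#'   the channels, so other values are rejected).
#' @param class_band_effects 3 x 5 matrix of log-power offsets per class
#'   (rownames "-1","0","1") and band; see [default_class_effects()].
#' @param drift_gain_sd sd of the per-session log-normal power gain.
#' @param drift_offset_sd sd of the per-session additive power offset.
#' @param channel_gain_sd sd of the per-subject log-normal channel gain
#'   profile (makes the channel dimension non-degenerate).
#' @param noise_floor baseline band power (power units).
#' @param seed integer; all randomness flows from it through per-entity
#'   substreams, so generation order is irrelevant.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_subjects = 15,
                             n_experiments_per_subject = 3,
                             sampling_rate = 200,
                             trial_duration = 180,
                             n_channels = 62,
                             class_band_effects = default_class_effects(),
                             drift_gain_sd = 0.4,
                             drift_offset_sd = 0.5,
                             channel_gain_sd = 0.1,
                             noise_floor = 1,
                             seed = 1L) {
  stopifnot(n_subjects >= 1, n_experiments_per_subject >= 1)
  if (n_channels != 62)
    stop("n_channels must be 62 (the montage defines the channel names)")
  if (sampling_rate < 2 * max(band_scheme()$high))
    stop("sampling_rate must be at least twice the gamma upper edge (50 Hz)")
  if (abs(trial_duration * sampling_rate - round(trial_duration * sampling_rate)) > 0)
    stop("trial_duration x sampling_rate must be an integer")
  if (!is.matrix(class_band_effects) ||
      !identical(dim(class_band_effects), c(3L, 5L)) ||
      !identical(rownames(class_band_effects), c("-1", "0", "1")))
    stop("class_band_effects must be a 3 x 5 matrix with rownames -1, 0, 1")
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_experiments_per_subject = as.integer(n_experiments_per_subject),
    n_trials = 15L,
    sampling_rate = sampling_rate,
    trial_duration = trial_duration,
    n_channels = 62L,
    class_band_effects = class_band_effects,
    drift_gain_sd = drift_gain_sd,
    drift_offset_sd = drift_offset_sd,
    channel_gain_sd = channel_gain_sd,
    noise_floor = noise_floor,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# Deterministic substream seed for an entity, independent of draw order.
# Mixes indices into [0, 2^31 - 2] by modular polynomial hashing.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in idx) {
    h <- (h * 69069 + as.numeric(k) * 10007 + 12345) %% 2147483647
  }
  as.integer(h)
}

# Run fn under a local RNG substream without disturbing the caller's RNG.
with_substream <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# Per-session drift: a multiplicative power gain and an additive power
# offset per (channel, band) cell, drawn once per (subject, experiment)
# and shared by all 15 trials. Per-channel variation emulates
# electrode-impedance/cap-placement differences between sessions, which
# act electrode by electrode, not globally.
session_drift <- function(config, subject_id, experiment_id) {
  nc <- config$n_channels
  with_substream(derive_seed(config$seed, 7L, subject_id, experiment_id), function() {
    g <- matrix(exp(stats::rnorm(nc * 5, 0, config$drift_gain_sd)), nc, 5)
    o <- matrix(stats::rnorm(nc * 5, 0, config$drift_offset_sd), nc, 5)
    rownames(g) <- rownames(o) <- seed_channel_names()
    list(gain = g, offset = o)
  })
}

# Per-subject fixed channel gain profile (log-normal), drawn once.
subject_channel_gains <- function(config, subject_id) {
  with_substream(derive_seed(config$seed, 11L, subject_id), function() {
    g <- exp(stats::rnorm(config$n_channels, 0, config$channel_gain_sd))
    names(g) <- seed_channel_names()
    g
  })
}

# Target band power for one (label, band, channel) under the generator model:
# noise_floor * exp(class effect) * channel gain * session cell gain +
# session cell offset, floored at a small positive fraction of the noise
# floor so the band process stays well defined.
target_band_power <- function(config, label, drift, channel_gains) {
  eff <- config$class_band_effects[as.character(label), ]
  base <- config$noise_floor * exp(eff)                    # per band
  p <- outer(channel_gains, base) * drift$gain + drift$offset
  pmax(p, 0.001 * config$noise_floor)                      # channels x bands
}

#' Generate one synthetic EEG trial
#'
#' The signal is a sum of five band-limited Gaussian processes, one per
#' canonical band, synthesized by zero-phase 4th-order Butterworth
#' band-pass filtering of white noise and rescaled so each band's variance
#' equals its target power under the generator model (class effect x
#' per-subject channel gain x per-session gain + per-session offset).
#'
#' @param config a [generator_config()].
#' @param subject_id,experiment_id positive integers.
#' @param trial_index trial position 0-14 (the label follows
#'   [emotion_order()] at this position).
#' @return a `raw_trial` list: `signal` (channels x samples matrix with
#'   channel rownames), `label`, `subject_id`, `experiment_id`,
#'   `trial_index`, `sampling_rate`.
#' @export
generate_trial <- function(config, subject_id, experiment_id, trial_index) {
  if (trial_index < 0 || trial_index > 14)
    stop("trial_index must be in 0..14")
  fs <- config$sampling_rate
  n <- round(config$trial_duration * fs)
  label <- emotion_order()[trial_index + 1]
  drift <- session_drift(config, subject_id, experiment_id)
  gains <- subject_channel_gains(config, subject_id)
  pow <- target_band_power(config, label, drift, gains)
  bands <- band_scheme()
  sig <- with_substream(
    derive_seed(config$seed, 3L, subject_id, experiment_id, trial_index),
    function() {
      out <- matrix(0, nrow = config$n_channels, ncol = n)
      for (b in seq_len(nrow(bands))) {
        flt <- signal::butter(4, c(bands$low[b], bands$high[b]) / (fs / 2),
                              type = "pass")
        for (ch in seq_len(config$n_channels)) {
          x <- signal::filtfilt(flt, stats::rnorm(n))
          v <- stats::var(x)
          if (v > 0) x <- x * sqrt(pow[ch, b] / v)
          out[ch, ] <- out[ch, ] + x
        }
      }
      out
    })
  rownames(sig) <- seed_channel_names()
  structure(list(
    signal = sig, label = label,
    subject_id = subject_id, experiment_id = experiment_id,
    trial_index = trial_index, sampling_rate = fs
  ), class = "raw_trial")
}

#' Generate a full synthetic dataset of raw-signal sessions
#'
#' @param config a [generator_config()].
#' @return list of experiment batches; each batch is a list with
#'   `subject_id`, `experiment_id`, `trials` (15 `raw_trial`s in
#'   presentation order), `labels`, and `drift` (the ground-truth session
#'   gain/offset, recorded for tests). The `generator_config` is attached
#'   as attribute `config`.
#' @export
generate_dataset <- function(config) {
  batches <- list()
  for (s in seq_len(config$n_subjects)) {
    for (e in seq_len(config$n_experiments_per_subject)) {
      trials <- lapply(0:14, function(ti) generate_trial(config, s, e, ti))
      batches[[length(batches) + 1]] <- list(
        subject_id = s, experiment_id = e,
        trials = trials,
        labels = emotion_order(),
        drift = session_drift(config, s, e)
      )
    }
  }
  attr(batches, "config") <- config
  batches
}

# 1-Hz periodogram bins falling in each band for fs = 1-s epochs (used to
# set the chi-square df of the feature-level simulator).
band_bin_counts <- function() {
  b <- band_scheme()
  as.integer(b$high - b$low + 1)
}

#' Simulate epoch-level band-power feature tensors directly
#'
#' Draws per-epoch band powers from the distribution the raw-signal
#' generator induces on the periodogram band-power estimator: a
#' band-limited Gaussian process of power P yields epoch band power
#' approximately P * chi-square(2m)/(2m), where m is the number of 1-Hz
#' bins in the band. This is the fast path for large, scaled pipeline runs
#' (no 62 x 36000 signals are materialised); statistical agreement with the
#' raw-signal path is asserted in the test suite.
#'
#' Class effects, per-subject channel gains and per-session drift enter the
#' target power exactly as in [generate_trial()]. The epoch noise substream
#' depends only on (seed, subject, experiment, trial), never on the drift
#' or effect values, so two configs that differ only in drift produce
#' feature sets related by the exact per-session power map.
#'
#' @param config a [generator_config()] (trial_duration must be 180 s).
#' @param feature_type `"psd"` (band power) or `"de"` (differential
#'   entropy, the Gaussian closed form of the band power).
#' @param lds apply LDS smoothing across epochs (default FALSE; the
#'   smoothing is deterministic and can be applied downstream).
#' @param lds_qr process/observation noise ratio for [lds_smooth()].
#' @return a feature dataset: list of experiments, each with `subject_id`,
#'   `experiment_id`, `labels`, `drift`, and `tensors` -- a list of 15
#'   arrays of dim (58, 5, 180) with channel/band dimnames and attributes
#'   `feature_type` and `experiment_key`.
#' @export
simulate_feature_dataset <- function(config, feature_type = c("psd", "de"),
                                     lds = FALSE, lds_qr = 0.01) {
  feature_type <- match.arg(feature_type)
  if (round(config$trial_duration) != 180)
    stop("feature tensors are defined for 180-s trials (180 one-second epochs)")
  keep <- match(retained_channels(), seed_channel_names())
  m <- band_bin_counts()
  n_ep <- 180L
  out <- list()
  for (s in seq_len(config$n_subjects)) {
    gains <- subject_channel_gains(config, s)
    for (e in seq_len(config$n_experiments_per_subject)) {
      drift <- session_drift(config, s, e)
      tensors <- vector("list", 15L)
      for (ti in 0:14) {
        label <- emotion_order()[ti + 1]
        pow <- target_band_power(config, label, drift, gains)[keep, , drop = FALSE]
        noise <- with_substream(
          derive_seed(config$seed, 5L, s, e, ti),
          function() {
            arr <- array(0, dim = c(58L, 5L, n_ep))
            for (b in 1:5) {
              df <- 2 * m[b]
              arr[, b, ] <- stats::rchisq(58L * n_ep, df = df) / df
            }
            arr
          })
        tens <- noise * array(rep(pow, n_ep), dim = c(58L, 5L, n_ep))
        if (lds) {
          for (ch in 1:58) for (b in 1:5)
            tens[ch, b, ] <- lds_smooth(tens[ch, b, ], qr_ratio = lds_qr)
        }
        if (feature_type == "de") tens <- de_from_power(tens)
        dimnames(tens) <- list(retained_channels(), band_scheme()$band, NULL)
        attr(tens, "feature_type") <- feature_type
        attr(tens, "experiment_key") <- experiment_key(s, e)
        tensors[[ti + 1]] <- tens
      }
      out[[length(out) + 1]] <- list(
        subject_id = s, experiment_id = e, labels = emotion_order(),
        drift = drift, tensors = tensors
      )
    }
  }
  attr(out, "config") <- config
  attr(out, "feature_type") <- feature_type
  out
}

# Canonical key identifying one recording session.
experiment_key <- function(subject_id, experiment_id) {
  sprintf("s%02d_e%d", subject_id, experiment_id)
}
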