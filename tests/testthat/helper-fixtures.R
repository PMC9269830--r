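# Shared fixtures and independent oracles, all built in code.

# Small feature-level dataset (fast path): `scale` sets class separability,
# drift sds set the session batch effect.
tiny_fds <- function(n_subjects = 2, n_experiments = 1, seed = 7,
                     feature_type = "psd", effect_scale = 1,
                     drift_gain_sd = 0, drift_offset_sd = 0) {
  cfg <- generator_config(
    n_subjects = n_subjects, n_experiments_per_subject = n_experiments,
    class_band_effects = default_class_effects(effect_scale),
    drift_gain_sd = drift_gain_sd, drift_offset_sd = drift_offset_sd,
    seed = seed
  )
  simulate_feature_dataset(cfg, feature_type = feature_type)
}

# A raw_trial built directly from a signal matrix (for segmentation and
# feature tests without running the generator).
make_trial <- function(signal, fs = 200, label = 1L, subject = 1L, exper = 1L,
                       trial_index = 0L) {
  rownames(signal) <- seed_channel_names()[seq_len(nrow(signal))]
  structure(list(signal = signal, label = label, subject_id = subject,
                 experiment_id = exper, trial_index = trial_index,
                 sampling_rate = fs),
            class = "raw_trial")
}

# Full-width constant-plus-noise signal of 62 channels.
random_signal <- function(n_samples, n_channels = 62, sd = 1, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_channels * n_samples, sd = sd), n_channels, n_samples)
}

# A 15-trial session of small TW tensors with a given window count,
# stamped with one experiment key.
toy_session <- function(n_windows = 4, seed = 1, key = "s01_e1") {
  set.seed(seed)
  lapply(1:15, function(i) {
    t <- array(rnorm(58 * 5 * n_windows), dim = c(58, 5, n_windows))
    attr(t, "experiment_key") <- key
    t
  })
}

# Independent Kruskal-Wallis oracle: tie-corrected H computed from first
# principles (midranks, rank sums, tie correction), no call to
# stats::kruskal.test.
kw_h_oracle <- function(values, groups) {
  r <- rank(values)           # midranks
  N <- length(values)
  h <- 0
  for (g in unique(groups)) {
    rg <- r[groups == g]
    h <- h + sum(rg)^2 / length(rg)
  }
  H <- 12 / (N * (N + 1)) * h - 3 * (N + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr > 0) H / corr else 0
}

# Brute-force sliding-window counter: walk the start positions.
count_windows_oracle <- function(duration, window, step) {
  n <- 0; start <- 0
  while (start + window <= duration) {
    n <- n + 1
    start <- start + step
  }
  n
}
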