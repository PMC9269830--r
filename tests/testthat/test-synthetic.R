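test_that("emotion order is the fixed 15-trial sequence with 5 per class", {
  ord <- emotion_order()
  expect_length(ord, 15)
  expect_identical(ord[1], 1L)   # first trial positive
  expect_identical(ord[3], -1L)  # third trial negative
  expect_identical(as.integer(table(ord)), c(5L, 5L, 5L))
  expect_identical(ord,
    c(1L, 0L, -1L, -1L, 0L, 1L, -1L, 0L, 1L, 1L, 0L, -1L, 0L, 1L, -1L))
})

test_that("generator config validates its invariants", {
  expect_error(generator_config(sampling_rate = 80), "twice")
  expect_error(generator_config(n_channels = 30), "62")
  expect_error(generator_config(trial_duration = 1.0001), "integer")
  expect_error(
    generator_config(class_band_effects = matrix(0, 2, 5)), "3 x 5")
})

test_that("dataset structure: batches, trials, labels, balance", {
  cfg <- generator_config(n_subjects = 2, n_experiments_per_subject = 2,
                          trial_duration = 5, seed = 3)
  ds <- generate_dataset(cfg)
  expect_length(ds, 4)
  expect_true(all(vapply(ds, function(b) length(b$trials), 0L) == 15L))
  for (b in ds) {
    labs <- vapply(b$trials, `[[`, 0L, "label")
    expect_identical(labs, emotion_order())
    expect_identical(as.integer(table(labs)), c(5L, 5L, 5L))
  }
})

test_that("generation is deterministic and order-independent", {
  cfg <- generator_config(n_subjects = 1, trial_duration = 3, seed = 11)
  t1 <- generate_trial(cfg, 1, 1, 4)
  t2 <- generate_trial(cfg, 1, 1, 4)
  expect_identical(t1$signal, t2$signal)
  # a different trial of the same session differs
  t3 <- generate_trial(cfg, 1, 1, 5)
  expect_false(identical(t1$signal[1, ], t3$signal[1, ]))
  # generating another trial in between does not disturb the substream
  junk <- generate_trial(cfg, 1, 1, 0)
  t4 <- generate_trial(cfg, 1, 1, 4)
  expect_identical(t1$signal, t4$signal)
  expect_error(generate_trial(cfg, 1, 1, 15), "0..14")
})

test_that("an injected alpha effect shifts measured alpha power by ~e", {
  eff <- default_class_effects(0)
  eff["1", "alpha"] <- 1
  cfg <- generator_config(n_subjects = 1, trial_duration = 20,
                          class_band_effects = eff,
                          drift_gain_sd = 0, drift_offset_sd = 0,
                          channel_gain_sd = 0, seed = 21)
  pos <- generate_trial(cfg, 1, 1, 0)   # label  1
  neu <- generate_trial(cfg, 1, 1, 1)   # label  0
  # independent band-power oracle: smoothed periodogram via spec.pgram
  alpha_power <- function(sig, fs) {
    mean(apply(sig, 1, function(x) {
      sp <- spec.pgram(ts(x, frequency = fs), taper = 0, plot = FALSE,
                       detrend = TRUE)
      2 * sum(sp$spec[sp$freq >= 8 & sp$freq <= 13]) * (sp$freq[2] - sp$freq[1])
    }))
  }
  ratio <- alpha_power(pos$signal, 200) / alpha_power(neu$signal, 200)
  expect_lt(abs(ratio - exp(1)) / exp(1), 0.1)
})

test_that("feature-level simulator matches signal-path band powers", {
  eff <- default_class_effects(1)
  cfg <- generator_config(n_subjects = 1, class_band_effects = eff,
                          drift_gain_sd = 0, drift_offset_sd = 0,
                          channel_gain_sd = 0, seed = 9)
  # signal path: one positive trial, mean measured band power per band
  tr <- generate_trial(cfg, 1, 1, 0)
  psd <- extract_features(tr, "psd")
  measured <- apply(psd, 2, mean)
  # target powers under the model: noise_floor * exp(effect)
  target <- cfg$noise_floor * exp(eff["1", ])
  # feature-level simulator for the same config
  fds <- simulate_feature_dataset(cfg, "psd")
  simulated <- apply(fds[[1]]$tensors[[1]], 2, mean)
  # both paths recover the injected per-band power structure; the Hann
  # periodogram loses a little band-edge energy to filter skirts
  expect_true(all(measured / target > 0.7 & measured / target < 1.05))
  expect_true(all(abs(simulated - target) / target < 0.1))
})

test_that("zero effects and drift give exchangeable trials; drift adds between-session variance", {
  fds0 <- tiny_fds(n_subjects = 4, seed = 31, effect_scale = 0)
  pow <- function(fds) vapply(unlist(lapply(fds, `[[`, "tensors"),
                                     recursive = FALSE),
                              function(t) mean(t[, "alpha", ]), 0)
  labs <- unlist(lapply(fds0, `[[`, "labels"))
  p0 <- pow(fds0)
  # class means agree within 3 standard errors
  for (cl in c(-1, 0, 1)) {
    x <- p0[labs == cl]; y <- p0[labs != cl]
    se <- sqrt(var(x) / length(x) + var(y) / length(y))
    expect_lt(abs(mean(x) - mean(y)), 3 * se)
  }
  # with drift, between-session variance dominates within-session variance
  fdsd <- tiny_fds(n_subjects = 4, seed = 31, effect_scale = 0,
                   drift_gain_sd = 0.8)
  pd <- pow(fdsd)
  sess <- rep(seq_along(fdsd), each = 15)
  between <- var(tapply(pd, sess, mean))
  within <- mean(tapply(pd, sess, var))
  expect_gt(between, within)
})
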