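test_that("segmentation yields 180 epochs and drops surplus samples", {
  # 180.5 s at 200 Hz: 36100 samples, last 100 dropped
  sig <- random_signal(36100)
  tr <- make_trial(sig)
  ep <- segment_epochs(tr)
  expect_identical(dim(ep), c(58L, 200L, 180L))
  # epoch k covers samples ((k-1)*fs, k*fs]: check on a ramp channel
  ramp <- sig
  ramp[1, ] <- seq_len(36100)   # row 1 is FP1 in montage order
  ep2 <- segment_epochs(make_trial(ramp))
  expect_identical(ep2["FP1", , 1], as.numeric(1:200))
  expect_identical(ep2["FP1", , 3], as.numeric(401:600))
  expect_identical(unname(ep2["FP1", 200, 180]), 36000)
})

test_that("segmentation rejects short trials and unnamed channels", {
  expect_error(segment_epochs(make_trial(random_signal(179 * 200))),
               "shorter than 180")
  sig <- random_signal(36000)
  tr <- make_trial(sig)
  rownames(tr$signal) <- NULL
  expect_error(segment_epochs(tr), "channel names")
  rownames(sig) <- seed_channel_names()
  rownames(sig)[1] <- "XX"
  tr2 <- make_trial(random_signal(36000))
  tr2$signal <- sig
  expect_error(segment_epochs(tr2), "FP1")
})

test_that("band power: zero signal, pure sinusoid, white-noise Parseval", {
  expect_identical(epoch_band_power(rep(0, 200), 200, 8, 13), 0)
  # unit-amplitude 10 Hz sinusoid: power A^2/2 = 0.5 lands in alpha
  x <- cos(2 * pi * 10 * (0:199) / 200)
  expect_lt(abs(epoch_band_power(x, 200, 8, 13) - 0.5), 0.005)
  expect_lt(epoch_band_power(x, 200, 31, 50), 1e-6)
  # Parseval: band powers over a full-spectrum partition sum to the
  # time-domain variance (averaged over many 1-s white-noise epochs)
  set.seed(42)
  n_ep <- 500
  tot <- 0; tvar <- 0
  for (i in seq_len(n_ep)) {
    e <- rnorm(200, sd = 2)
    tot <- tot + epoch_band_power(e, 200, 0, 100)
    tvar <- tvar + mean((e - mean(e))^2)
  }
  expect_lt(abs(tot - tvar) / tvar, 0.01)
  expect_error(epoch_band_power(c(1, NA, 3), 200, 1, 3), "non-finite")
})

test_that("differential entropy follows the Gaussian closed form", {
  # DE = 0 exactly at P = 1/(2*pi*e)
  x <- sqrt(1 / (2 * pi * exp(1))) * cos(2 * pi * 10 * (0:199) / 200) * sqrt(2)
  p <- epoch_band_power(x, 200, 8, 13)
  expect_lt(abs(eegtw:::de_from_power(p)), 0.02)
  expect_identical(eegtw:::de_from_power(1 / (2 * pi * exp(1))), 0)
  # frozen closed-form value at P = 1 (0.5 * ln(2*pi*e))
  expect_equal(eegtw:::de_from_power(1), 1.418938533204673, tolerance = 1e-12)
  # doubling the power adds exactly 0.5 * ln 2
  expect_equal(eegtw:::de_from_power(2) - eegtw:::de_from_power(1),
               0.5 * log(2), tolerance = 1e-12)
  # nonpositive power clips to a floor with a warning
  expect_warning(v <- eegtw:::de_from_power(0), "clipped")
  expect_true(is.finite(v))
})

test_that("LDS smoothing: fixed points, limits, variance reduction", {
  expect_identical(lds_smooth(rep(3.5, 180)), rep(3.5, 180))
  set.seed(5)
  y <- rnorm(180)
  # q/r -> infinity approaches the identity
  expect_equal(lds_smooth(y, qr_ratio = 1e8), y, tolerance = 1e-3)
  # strong smoothing reduces the sample variance of white noise
  s <- lds_smooth(y, qr_ratio = 0.01)
  expect_lt(var(s), var(y))
  expect_length(s, 180)
  expect_error(lds_smooth(c(1, Inf)), "non-finite")
})

test_that("extract_features composes the stages and links PSD to DE", {
  tr <- make_trial(random_signal(36000, sd = 1.3), label = 1L)
  psd <- extract_features(tr, "psd")
  de <- extract_features(tr, "de")
  expect_identical(dim(psd), c(58L, 5L, 180L))
  expect_true(all(psd >= 0))
  expect_identical(attr(psd, "feature_type"), "psd")
  expect_identical(attr(psd, "experiment_key"), "s01_e1")
  # DE = 0.5 * ln(2*pi*e*PSD) entrywise when neither is smoothed
  expect_equal(as.vector(de), as.vector(0.5 * log(2 * pi * exp(1) * psd)),
               tolerance = 1e-12)
  # ordering preservation follows from the monotone link
  ord_p <- order(psd[1, 1, ]); ord_d <- order(de[1, 1, ])
  expect_identical(ord_p, ord_d)
  # smoothing never changes the shape
  sm <- extract_features(tr, "psd", lds = TRUE)
  expect_identical(dim(sm), c(58L, 5L, 180L))
  expect_false(identical(as.vector(sm), as.vector(psd)))
})
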