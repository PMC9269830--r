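test_that("fitted extrema match a brute-force scan and map to 0/1", {
  sess <- toy_session(n_windows = 4, seed = 2)
  stats <- fit_elbn(sess)
  # brute-force extrema per (channel, band) over all 15 x 4 window values
  for (ch in c(1, 20, 58)) for (b in 1:5) {
    vals <- unlist(lapply(sess, function(t) t[ch, b, ]))
    expect_identical(stats$fmin[ch, b], min(vals))
    expect_identical(stats$fmax[ch, b], max(vals))
  }
  norm <- lapply(sess, apply_elbn, stats = stats)
  all_norm <- unlist(norm)
  expect_true(all(all_norm >= 0 & all_norm <= 1))
  # the session minimum maps to exactly 0 and the maximum to exactly 1
  expect_identical(min(all_norm), 0)
  expect_identical(max(all_norm), 1)
  for (ch in c(1, 58)) for (b in 1:5) {
    vals <- unlist(lapply(norm, function(t) t[ch, b, ]))
    expect_identical(min(vals), 0)
    expect_identical(max(vals), 1)
  }
})

test_that("toy values {2,4,6} normalize to {0, 0.5, 1}", {
  sess <- toy_session(n_windows = 1, seed = 3)
  for (i in 1:15) sess[[i]][1, 1, 1] <- c(2, 4, 6)[(i - 1) %% 3 + 1]
  norm <- eegtw:::elbn_normalize_session(sess)
  got <- vapply(norm, function(t) t[1, 1, 1], 0)
  expect_equal(got, rep(c(0, 0.5, 1), 5), tolerance = 1e-12)
})

test_that("ELBN is idempotent and exactly affine-invariant", {
  sess <- toy_session(n_windows = 3, seed = 4)
  norm1 <- eegtw:::elbn_normalize_session(sess)
  norm2 <- eegtw:::elbn_normalize_session(norm1)
  expect_equal(lapply(norm2, as.vector), lapply(norm1, as.vector),
               tolerance = 1e-12)
  # per-(channel, band) affine distortion a*F + b with a > 0, applied to
  # the whole session, leaves the normalized values unchanged exactly
  set.seed(10)
  a <- matrix(runif(58 * 5, 0.5, 3), 58, 5)
  b <- matrix(rnorm(58 * 5, 0, 10), 58, 5)
  warped <- lapply(sess, function(t) {
    w <- t * array(rep(a, 3), dim = dim(t)) + array(rep(b, 3), dim = dim(t))
    attr(w, "experiment_key") <- attr(t, "experiment_key")
    w
  })
  normw <- eegtw:::elbn_normalize_session(warped)
  expect_equal(lapply(normw, as.vector), lapply(norm1, as.vector),
               tolerance = 1e-9)
})

test_that("degenerate ranges give 0 and provenance mismatches error", {
  sess <- toy_session(n_windows = 2, seed = 5)
  for (i in 1:15) sess[[i]][7, 3, ] <- 4.2   # constant cell
  norm <- eegtw:::elbn_normalize_session(sess)
  expect_true(all(vapply(norm, function(t) all(t[7, 3, ] == 0), TRUE)))
  # stats from another session are refused
  stats <- fit_elbn(sess)
  other <- toy_session(n_windows = 2, seed = 6, key = "s02_e1")
  expect_error(apply_elbn(other[[1]], stats), "within-experiment")
  # a session must hold exactly 15 trials from one experiment
  expect_error(fit_elbn(sess[1:14]), "15 trials")
  mixed <- c(sess[1:14], other[1])
  expect_error(fit_elbn(mixed), "more than one session")
})

test_that("per-window-index pooling matches all-window pooling at N = 1", {
  sess <- toy_session(n_windows = 1, seed = 11)
  n_all <- eegtw:::elbn_normalize_session(sess, pooling = "all_windows")
  n_pw <- eegtw:::elbn_normalize_session(sess, pooling = "per_window_index")
  expect_equal(lapply(n_all, as.vector), lapply(n_pw, as.vector),
               tolerance = 1e-12)
  # at N > 1 the per-window variant normalizes each window position alone
  sess3 <- toy_session(n_windows = 3, seed = 12)
  stats <- fit_elbn(sess3, pooling = "per_window_index")
  expect_identical(dim(stats$fmin), c(58L, 5L, 3L))
  vals <- vapply(sess3, function(t) t[1, 1, 2], 0)
  norm <- lapply(sess3, apply_elbn, stats = stats)
  got <- vapply(norm, function(t) t[1, 1, 2], 0)
  expect_equal(got, (vals - min(vals)) / (max(vals) - min(vals)),
               tolerance = 1e-12)
})

test_that("normalization is strictly within-experiment", {
  s1 <- toy_session(n_windows = 2, seed = 13, key = "s01_e1")
  s2 <- toy_session(n_windows = 2, seed = 14, key = "s02_e1")
  # normalizing s1 alone or alongside any other session gives the same
  n_alone <- eegtw:::elbn_normalize_session(s1)
  n_again <- eegtw:::elbn_normalize_session(s1)
  expect_identical(lapply(n_alone, as.vector), lapply(n_again, as.vector))
  # and s2's values never enter s1's stats
  stats1 <- fit_elbn(s1)
  big <- lapply(s2, function(t) t * 1000)
  expect_identical(fit_elbn(s1)$fmax, stats1$fmax)
})
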