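test_that("the ten split sets reproduce the published design", {
  sets <- split_sets(quiet = TRUE)
  expect_length(sets, 10)
  for (s in sets) {
    expect_length(s$train, 12)
    expect_length(s$test, 3)
    expect_true(all(c(s$train, s$test) %in% 0:14))
    # every test triple holds one trial per emotion class
    labs <- emotion_order()[s$test + 1]
    expect_identical(sort(labs), c(-1L, 0L, 1L))
  }
  expect_identical(sets[[1]]$test, c(3L, 7L, 8L))
  # set 3 carries the verbatim train/test overlap on trial 12
  expect_identical(intersect(sets[[3]]$train, sets[[3]]$test), 12L)
  ov <- vapply(sets, function(s) length(intersect(s$train, s$test)), 0L)
  expect_identical(which(ov > 0), 3L)
  expect_message(split_sets(), "both train and test")
})

test_that("samples are one flattened trial vector each", {
  fds <- tiny_fds(n_subjects = 1, seed = 17)
  s180 <- build_samples(fds, 180)
  expect_identical(dim(s180$x), c(15L, 290L))        # 58 * 5 * 1
  expect_identical(dim(build_samples(fds, 2)$x), c(15L, 26100L))
  expect_identical(as.integer(table(s180$y)), c(5L, 5L, 5L))
  expect_identical(s180$trial_index, 0:14)
  # flattening order is (channel, band, window), channel fastest
  tens <- aggregate_tw(fds[[1]]$tensors[[1]], 180)
  expect_identical(s180$x[1, 59:116], unname(tens[, 2, 1]))
  # restricting to one band cuts the vector to 58 * N
  s_alpha <- build_samples(fds, 180, bands = "alpha")
  expect_identical(dim(s_alpha$x), c(15L, 58L))
  expect_identical(s_alpha$x[3, ], unname(aggregate_tw(
    fds[[1]]$tensors[[3]], 180)[, "alpha", 1]))
})

test_that("accuracy is invariant to experiment order and, with ELBN, to scale", {
  fds <- tiny_fds(n_subjects = 2, seed = 23, effect_scale = 1.5)
  splits <- split_sets(quiet = TRUE)[1:3]
  spec <- classifier_specs()["lr"]
  r1 <- evaluate_grid(fds, tw_lengths = 180, specs = spec, splits = splits)
  r2 <- evaluate_grid(rev(fds), tw_lengths = 180, specs = spec, splits = splits)
  expect_identical(r1$accuracy, r2$accuracy)
  # multiplying every feature of one experiment by a positive constant
  # changes no accuracy once ELBN is on
  fds_scaled <- fds
  fds_scaled[[2]]$tensors <- lapply(fds_scaled[[2]]$tensors, function(t) {
    out <- t * 7.3
    attributes(out) <- attributes(t)
    out
  })
  a1 <- evaluate_grid(fds, tw_lengths = 180, specs = spec, splits = splits,
                      elbn = "paper")
  a2 <- evaluate_grid(fds_scaled, tw_lengths = 180, specs = spec,
                      splits = splits, elbn = "paper")
  expect_identical(a1$accuracy, a2$accuracy)
})

test_that("grid output has one cell per tw x classifier x set with confusion", {
  fds <- tiny_fds(n_subjects = 1, seed = 29, effect_scale = 2)
  splits <- split_sets(quiet = TRUE)[1:2]
  specs <- classifier_specs(bagging_estimators = 5)[c("knn", "lr")]
  res <- evaluate_grid(fds, tw_lengths = c(180, 30), specs = specs,
                       splits = splits)
  expect_identical(nrow(res), 2L * 2L * 2L)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  conf <- attr(res, "confusion")
  expect_length(conf, 8)
  expect_true(all(vapply(conf, sum, 0) == 3))   # 3 test trials, 1 experiment
  smry <- summarize_accuracy(res)
  expect_identical(nrow(smry), 4L)
  expect_true(all(smry$mean_pct >= 0 & smry$mean_pct <= 100))
  m <- accuracy_matrix(smry)
  expect_identical(dim(m), c(2L, 2L))
  pc <- per_class_accuracy(res)
  expect_identical(nrow(pc), 8L * 3L)
  expect_true(all(pc$class_accuracy >= 0 & pc$class_accuracy <= 1))
})

test_that("causal ELBN fits extrema on training trials only", {
  fds <- tiny_fds(n_subjects = 1, seed = 31)
  split <- split_sets(quiet = TRUE)[[1]]
  sc <- build_samples(fds, 180, elbn = "causal", split = split)
  sp <- build_samples(fds, 180, elbn = "paper")
  # train-trial features may exceed [0,1] in neither mode...
  tr_rows <- sc$trial_index %in% split$train
  expect_true(all(sc$x[tr_rows, ] >= 0 & sc$x[tr_rows, ] <= 1))
  # ...but causal test-trial features can escape the training range
  expect_true(any(sc$x < 0 | sc$x > 1))
  expect_false(identical(sc$x, sp$x))
  expect_error(build_samples(fds, 180, elbn = "causal"), "requires a split")
})

test_that("the ELBN contrast table diffs summaries and locates the argmax", {
  s1 <- data.frame(tw_length = c(2, 2), classifier = c("LR", "SVM"),
                   mean_pct = c(60, 50), sd_pct = c(1, 1))
  s2 <- data.frame(tw_length = c(2, 2), classifier = c("LR", "SVM"),
                   mean_pct = c(70, 72), sd_pct = c(1, 1))
  expect_true(all(elbn_contrast(s1, s1)$improvement_pct == 0))
  con <- elbn_contrast(s1, s2)
  expect_equal(con$improvement_pct[con$classifier == "SVM"], 22)
  am <- attr(con, "argmax")
  expect_identical(am$classifier, "SVM")
  expect_equal(am$improvement_pct, 22)
  s3 <- s2[1, ]
  expect_error(elbn_contrast(s1, s3), "different")
})
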