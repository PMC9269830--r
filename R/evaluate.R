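#' The ten fixed train/test trial splits
#'
#' The published 10 random sets, applied identically in every experiment:
#' 12 trials train, 3 test (trials numbered 0-14). Set 3 places trial 12
#' in both its training and its testing list; the overlap is reproduced
#' verbatim and reported via a message.
#'
#' @param quiet suppress the overlap message.
#' @return list of 10 splits, each `list(set_id, train, test)` with
#'   0-based trial indices.
#' @export
split_sets <- function(quiet = FALSE) {
  sets <- list(
    list(set_id = 1L, train = c(0L,1L,2L,4L,5L,6L,9L,10L,11L,12L,13L,14L), test = c(3L,7L,8L)),
    list(set_id = 2L, train = c(0L,1L,2L,3L,6L,7L,8L,9L,10L,12L,13L,14L), test = c(4L,5L,11L)),
    list(set_id = 3L, train = c(1L,3L,4L,5L,6L,7L,8L,9L,10L,11L,12L,14L), test = c(0L,2L,12L)),
    list(set_id = 4L, train = c(0L,1L,3L,4L,5L,6L,7L,8L,9L,10L,11L,14L), test = c(2L,12L,13L)),
    list(set_id = 5L, train = c(0L,1L,2L,3L,4L,5L,7L,9L,10L,11L,13L,14L), test = c(6L,8L,12L)),
    list(set_id = 6L, train = c(0L,1L,2L,5L,6L,7L,9L,10L,11L,12L,13L,14L), test = c(3L,4L,8L)),
    list(set_id = 7L, train = c(0L,1L,2L,3L,4L,6L,7L,8L,9L,11L,12L,13L), test = c(5L,10L,14L)),
    list(set_id = 8L, train = c(0L,2L,3L,4L,5L,7L,9L,10L,11L,12L,13L,14L), test = c(1L,6L,8L)),
    list(set_id = 9L, train = c(0L,3L,4L,5L,6L,7L,8L,10L,11L,12L,13L,14L), test = c(1L,2L,9L)),
    list(set_id = 10L, train = c(0L,1L,2L,3L,4L,5L,6L,8L,10L,11L,12L,13L), test = c(7L,9L,14L))
  )
  if (!quiet) {
    for (s in sets) {
      ov <- intersect(s$train, s$test)
      if (length(ov) > 0)
        message("split set ", s$set_id, ": trial(s) ",
                paste(ov, collapse = ", "), " appear in both train and test ",
                "(reproduced verbatim from the published design)")
    }
  }
  sets
}

# Aggregate every trial of a feature dataset to one TW length.
# Returns list of experiments, each with `tensors` replaced by the
# (58, 5, N) TW arrays.
tw_tensors <- function(fds, tw_length) {
  lapply(fds, function(exp) {
    exp$tensors <- lapply(exp$tensors, aggregate_tw, tw_length = tw_length)
    exp
  })
}

# Flatten a list of TW-aggregated experiments into a sample matrix.
# Vector order is (channel, band, window), channel fastest -- the natural
# column-major order of the (58, 5, N) array. `bands` optionally restricts
# to a subset of band names (the per-band evaluation mode).
flatten_samples <- function(tw_exps, bands = NULL) {
  rows <- list(); y <- integer(0); trial <- integer(0); expkey <- character(0)
  for (e in tw_exps) {
    for (i in seq_along(e$tensors)) {
      t <- e$tensors[[i]]
      if (!is.null(bands)) t <- t[, bands, , drop = FALSE]
      rows[[length(rows) + 1]] <- as.vector(t)
      y <- c(y, e$labels[i])
      trial <- c(trial, i - 1L)              # 0-based, matching split_sets()
      expkey <- c(expkey, experiment_key(e$subject_id, e$experiment_id))
    }
  }
  list(x = do.call(rbind, rows),
       y = factor(y, levels = c(-1, 0, 1)),
       trial_index = trial,
       experiment = expkey)
}

#' Build trial-level samples at one TW length
#'
#' One sample per trial: the flattened (58, 5, N) TW tensor (features from
#' all five bands concatenated), in fixed (channel, band, window) order.
#' ELBN, when on, is fitted and applied within each experiment before
#' flattening.
#'
#' @param fds a feature dataset ([simulate_feature_dataset()] or
#'   [extract_feature_dataset()]).
#' @param tw_length one of the 11 TW lengths.
#' @param elbn `"off"`, `"paper"` (fit on all 15 trials, the published
#'   protocol), or `"causal"` (fit on training trials only; requires
#'   `split`).
#' @param pooling ELBN pooling granularity, see [fit_elbn()].
#' @param split a split (from [split_sets()]) -- required for causal ELBN.
#' @param bands optional character vector of band names to restrict the
#'   feature vector to (per-band evaluation mode); default all five.
#' @return list with `x` (n x p matrix), `y` (factor -1/0/1),
#'   `trial_index` (0-based), `experiment` (session keys).
#' @export
build_samples <- function(fds, tw_length, elbn = c("off", "paper", "causal"),
                          pooling = "all_windows", split = NULL, bands = NULL) {
  elbn <- match.arg(elbn)
  tws <- tw_tensors(fds, tw_length)
  if (elbn == "paper") {
    tws <- lapply(tws, function(e) {
      e$tensors <- elbn_normalize_session(e$tensors, pooling = pooling)
      e
    })
  } else if (elbn == "causal") {
    if (is.null(split)) stop("causal ELBN requires a split")
    tws <- lapply(tws, function(e) {
      stats <- fit_elbn_subset(e$tensors, split$train, pooling = pooling)
      e$tensors <- lapply(e$tensors, apply_elbn, stats = stats)
      e
    })
  }
  flatten_samples(tws, bands = bands)
}

# Causal ELBN: extrema from the training trials only. Fitting reuses
# fit_elbn's pooling on the subset, then stamps the session key.
fit_elbn_subset <- function(tensors, train_idx, pooling = "all_windows") {
  sub <- tensors[train_idx + 1L]
  d <- dim(sub[[1]])
  stacked <- array(unlist(sub, use.names = FALSE), dim = c(d, length(sub)))
  if (pooling == "all_windows") {
    flat <- matrix(stacked, nrow = d[1] * d[2])
    fmin <- matrix(apply(flat, 1, min), d[1], d[2])
    fmax <- matrix(apply(flat, 1, max), d[1], d[2])
  } else {
    fmin <- apply(stacked, c(1, 2, 3), min)
    fmax <- apply(stacked, c(1, 2, 3), max)
  }
  structure(list(fmin = fmin, fmax = fmax, pooling = pooling,
                 experiment_key = attr(tensors[[1]], "experiment_key")),
            class = "elbn_stats")
}

#' Offline evaluation grid: TW lengths x classifiers x split sets
#'
#' For each TW length, classifier and split set, trains on the 12 training
#' trials of every experiment and tests on the 3 test trials, reporting
#' overall accuracy. Wide sample matrices are row-space reduced (exact for
#' all backends except GNB, which sees the original features).
#'
#' @param fds feature dataset.
#' @param tw_lengths TW lengths to evaluate (default all 11).
#' @param specs classifier specs (default [classifier_specs()]).
#' @param splits split sets (default [split_sets()]).
#' @param elbn,pooling,bands passed to [build_samples()].
#' @param reduce apply [reduce_rowspace()] to wide matrices (default TRUE).
#' @return data.frame with columns `tw_length`, `classifier`, `set_id`,
#'   `accuracy` (fraction correct), plus attribute `confusion`: a named
#'   list of 3 x 3 confusion matrices (true x predicted), one per cell.
#' @export
evaluate_grid <- function(fds, tw_lengths = tw_table()$tw_length,
                          specs = classifier_specs(),
                          splits = split_sets(quiet = TRUE),
                          elbn = c("off", "paper", "causal"),
                          pooling = "all_windows", bands = NULL,
                          reduce = TRUE) {
  elbn <- match.arg(elbn)
  res <- list()
  confusion <- list()
  for (tw in tw_lengths) {
    if (elbn != "causal") {
      smp <- build_samples(fds, tw, elbn = elbn, pooling = pooling,
                           bands = bands)
      xr <- if (reduce) reduce_rowspace(smp$x) else smp$x
    }
    for (split in splits) {
      if (elbn == "causal") {
        smp <- build_samples(fds, tw, elbn = "causal", pooling = pooling,
                             split = split, bands = bands)
        xr <- if (reduce) reduce_rowspace(smp$x) else smp$x
      }
      tr <- smp$trial_index %in% split$train
      te <- smp$trial_index %in% split$test
      for (spec in specs) {
        xm <- if (spec$rotation_invariant) xr else smp$x
        model <- tryCatch(
          train_classifier(spec, xm[tr, , drop = FALSE], smp$y[tr]),
          error = function(e) stop("classifier ", spec$name, " failed at tw=",
                                   tw, " set=", split$set_id, ": ",
                                   conditionMessage(e)))
        pred <- predict_classifier(model, xm[te, , drop = FALSE])
        truth <- smp$y[te]
        cell <- sprintf("tw%s_%s_set%d", tw, spec$name, split$set_id)
        confusion[[cell]] <- table(truth = truth, pred = pred)
        res[[length(res) + 1]] <- data.frame(
          tw_length = tw, classifier = spec$name, set_id = split$set_id,
          accuracy = mean(pred == truth)
        )
      }
    }
  }
  out <- do.call(rbind, res)
  attr(out, "confusion") <- confusion
  out
}

#' Summarize an evaluation grid over the split sets
#'
#' @param results output of [evaluate_grid()].
#' @return data.frame per (tw_length, classifier): `mean_pct` and `sd_pct`,
#'   accuracy in percent over the split sets.
#' @export
summarize_accuracy <- function(results) {
  agg <- stats::aggregate(accuracy ~ tw_length + classifier, data = results,
                          FUN = function(a) c(mean = mean(a), sd = stats::sd(a)))
  out <- data.frame(
    tw_length = agg$tw_length,
    classifier = agg$classifier,
    mean_pct = 100 * agg$accuracy[, "mean"],
    sd_pct = 100 * agg$accuracy[, "sd"]
  )
  rownames(out) <- NULL
  out
}

#' Render a summary as a publication-style "mean(sd)" matrix
#'
#' @param summary output of [summarize_accuracy()].
#' @return character matrix, rows = TW length (180 s down to 1 s),
#'   columns = classifier.
#' @export
accuracy_matrix <- function(summary) {
  tws <- sort(unique(summary$tw_length), decreasing = TRUE)
  cls <- unique(summary$classifier)
  m <- matrix("", length(tws), length(cls), dimnames = list(tws, cls))
  for (i in seq_len(nrow(summary))) {
    m[as.character(summary$tw_length[i]), summary$classifier[i]] <-
      sprintf("%.2f(%.2f)", summary$mean_pct[i], summary$sd_pct[i])
  }
  m
}

#' Per-class accuracy from a grid's confusion matrices
#'
#' @param results output of [evaluate_grid()].
#' @return data.frame per (tw_length, classifier, set_id, class):
#'   `class_accuracy`.
#' @export
per_class_accuracy <- function(results) {
  conf <- attr(results, "confusion")
  rows <- list()
  for (nm in names(conf)) {
    cm <- conf[[nm]]
    parts <- strsplit(nm, "_")[[1]]
    acc <- diag(cm) / pmax(rowSums(cm), 1)
    rows[[nm]] <- data.frame(
      tw_length = as.numeric(sub("tw", "", parts[1])),
      classifier = parts[2],
      set_id = as.integer(sub("set", "", parts[3])),
      class = rownames(cm),
      class_accuracy = as.numeric(acc)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Contrast two evaluation summaries (with vs without ELBN)
#'
#' @param without,with outputs of [summarize_accuracy()] on the same grid.
#' @return data.frame per (tw_length, classifier) with `improvement_pct`
#'   (percentage points, with minus without); attribute `argmax` names the
#'   cell with the largest improvement.
#' @export
elbn_contrast <- function(without, with) {
  m <- merge(without, with, by = c("tw_length", "classifier"),
             suffixes = c("_without", "_with"))
  if (nrow(m) != nrow(without) || nrow(m) != nrow(with))
    stop("grids have different (tw_length, classifier) cells")
  out <- data.frame(
    tw_length = m$tw_length,
    classifier = m$classifier,
    improvement_pct = m$mean_pct_with - m$mean_pct_without
  )
  best <- out[which.max(out$improvement_pct), ]
  attr(out, "argmax") <- list(classifier = as.character(best$classifier),
                              tw_length = best$tw_length,
                              improvement_pct = best$improvement_pct)
  out
}
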