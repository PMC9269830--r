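#' Number of sliding windows in a trial
#'
#' floor((duration - window) / step) + 1; a 180-s trial with a 2-s window
#' and 1-s step yields 179 windows.
#'
#' @param duration_s,window_s,step_s seconds (whole epochs).
#' @return integer window count.
#' @export
count_windows <- function(duration_s, window_s, step_s) {
  if (window_s > duration_s) stop("window longer than trial duration")
  if (step_s <= 0) stop("step must be positive")
  as.integer(floor((duration_s - window_s) / step_s) + 1)
}

#' Sliding-window feature tensor of one trial
#'
#' Window w (1-based) averages epochs (w-1)*step + 1 .. (w-1)*step + window
#' per channel and band, producing a (58, 5, W) array; consecutive windows
#' overlap in window - step epochs.
#'
#' @param tensor (58, 5, 180) epoch feature tensor.
#' @param window,step window length and step in whole epochs (seconds).
#' @return (58, 5, W) array with attributes carried over.
#' @export
online_tw_tensor <- function(tensor, window = 2, step = 1) {
  d <- dim(tensor)
  W <- count_windows(d[3], window, step)
  out <- array(0, dim = c(d[1], d[2], W), dimnames = dimnames(tensor))
  flat <- matrix(tensor, nrow = d[1] * d[2])
  for (w in seq_len(W)) {
    cols <- ((w - 1) * step + 1):((w - 1) * step + window)
    out[, , w] <- if (length(cols) == 1) flat[, cols]
                  else rowMeans(flat[, cols, drop = FALSE])
  }
  for (a in c("feature_type", "lds", "experiment_key"))
    attr(out, a) <- attr(tensor, a)
  out
}

#' Sliding-window feature vectors of one trial
#'
#' Aggregates with [online_tw_tensor()], optionally normalizes with the
#' session's ELBN stats, and flattens each window to a length-290 vector
#' (58 channels x 5 bands, channel fastest).
#'
#' @param tensor (58, 5, 180) epoch feature tensor.
#' @param window,step sliding-window parameters in epochs.
#' @param elbn_stats optional `elbn_stats` for the trial's session.
#' @return W x 290 matrix.
#' @export
online_features <- function(tensor, window = 2, step = 1, elbn_stats = NULL) {
  arr <- online_tw_tensor(tensor, window, step)
  if (!is.null(elbn_stats)) arr <- apply_elbn(arr, elbn_stats)
  t(matrix(arr, nrow = dim(arr)[1] * dim(arr)[2]))
}

#' Sliding-window online emotion recognition
#'
#' For each split set, trains the logistic-regression classifier on the
#' window-level features (58 x 5 per window) of the 12 training trials of
#' every experiment, then emits a W x 3 class-probability trace for each
#' test trial. ELBN, when on, uses within-session extrema fitted over all
#' sliding windows of the session's 15 trials (the published, leaky
#' protocol); `elbn = "causal"` restricts the extrema to training trials.
#'
#' @param fds feature dataset.
#' @param splits split sets (default the 10 published ones).
#' @param window,step sliding-window parameters in seconds (defaults 2, 1).
#' @param elbn `"off"`, `"paper"`, or `"causal"`.
#' @param pooling ELBN pooling granularity.
#' @param spec classifier spec (default LR).
#' @return list with:
#'   `traces` -- long data.frame (set_id, experiment, trial_index,
#'   window_index, time_s, p_neg, p_neu, p_pos, true_label, pred);
#'   `summary` -- per (true_label, window_index, class) 25th/50th/75th
#'   percentile of the predicted probability across test trials and sets
#'   (the quantities behind the online-recognition trajectory figures);
#'   `accuracy` -- per-set mean window-level accuracy;
#'   `n_windows` -- windows per trial.
#' @export
run_online <- function(fds, splits = split_sets(quiet = TRUE),
                       window = 2, step = 1,
                       elbn = c("paper", "off", "causal"),
                       pooling = "all_windows",
                       spec = classifier_specs()$lr) {
  elbn <- match.arg(elbn)
  W <- count_windows(180, window, step)
  # per experiment: sliding tensors, normalized per the ELBN mode
  prep <- lapply(fds, function(e) {
    arrs <- lapply(e$tensors, online_tw_tensor, window = window, step = step)
    e$arrs <- arrs
    e
  })
  traces <- list()
  acc <- numeric(0)
  for (split in splits) {
    xs <- list(); ys <- integer(0)
    test_rows <- list()
    for (e in prep) {
      arrs <- e$arrs
      if (elbn == "paper") {
        arrs <- elbn_normalize_session(arrs, pooling = pooling)
      } else if (elbn == "causal") {
        stats <- fit_elbn_subset(arrs, split$train, pooling = pooling)
        arrs <- lapply(arrs, apply_elbn, stats = stats)
      }
      mats <- lapply(arrs, function(a) t(matrix(a, nrow = dim(a)[1] * dim(a)[2])))
      for (ti in split$train) {
        xs[[length(xs) + 1]] <- mats[[ti + 1]]
        ys <- c(ys, rep(e$labels[ti + 1], W))
      }
      for (ti in split$test) {
        test_rows[[length(test_rows) + 1]] <- list(
          experiment = experiment_key(e$subject_id, e$experiment_id),
          trial_index = ti, x = mats[[ti + 1]], label = e$labels[ti + 1])
      }
    }
    xtr <- do.call(rbind, xs)
    ytr <- factor(ys, levels = c(-1, 0, 1))
    model <- train_classifier(spec, xtr, ytr)
    correct <- 0; total <- 0
    for (tr in test_rows) {
      pr <- predict_classifier(model, tr$x, type = "prob")
      pred <- factor(colnames(pr)[max.col(pr, ties.method = "first")],
                     levels = c(-1, 0, 1))
      correct <- correct + sum(pred == as.character(tr$label))
      total <- total + nrow(pr)
      traces[[length(traces) + 1]] <- data.frame(
        set_id = split$set_id, experiment = tr$experiment,
        trial_index = tr$trial_index, window_index = seq_len(W),
        time_s = (seq_len(W) - 1) * step,
        p_neg = pr[, "-1"], p_neu = pr[, "0"], p_pos = pr[, "1"],
        true_label = tr$label, pred = as.integer(as.character(pred))
      )
    }
    acc <- c(acc, correct / total)
  }
  traces <- do.call(rbind, traces)
  rownames(traces) <- NULL
  summary <- online_trace_summary(traces)
  list(traces = traces,
       summary = summary,
       accuracy = data.frame(set_id = vapply(splits, `[[`, 0L, "set_id"),
                             window_accuracy = acc),
       n_windows = W)
}

#' Percentile trajectories of online class probabilities
#'
#' @param traces the `traces` data.frame from [run_online()].
#' @return data.frame per (true_label, window_index, class): `q25`,
#'   `median`, `q75` of the predicted probability across test trials/sets.
#' @export
online_trace_summary <- function(traces) {
  rows <- list()
  probs <- c("-1" = "p_neg", "0" = "p_neu", "1" = "p_pos")
  for (lab in unique(traces$true_label)) {
    sub <- traces[traces$true_label == lab, ]
    for (cls in names(probs)) {
      q <- stats::aggregate(sub[[probs[[cls]]]],
                            by = list(window_index = sub$window_index),
                            FUN = stats::quantile, probs = c(0.25, 0.5, 0.75))
      rows[[length(rows) + 1]] <- data.frame(
        true_label = lab, window_index = q$window_index, class = cls,
        q25 = q$x[, 1], median = q$x[, 2], q75 = q$x[, 3]
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
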