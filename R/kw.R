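#' Per-trial mean feature per channel and band
#'
#' Mean over a trial's TW window values per (channel, band). By the
#' equal-window conservation property this equals the mean over all 180
#' epoch values whenever no window-dependent transform (such as ELBN at
#' N > 1) intervenes.
#'
#' @param tensor (58, 5, N) TW feature array.
#' @return 58 x 5 matrix.
#' @export
trial_mean_features <- function(tensor) {
  d <- dim(tensor)
  m <- matrix(rowMeans(matrix(tensor, nrow = d[1] * d[2])), d[1], d[2])
  dimnames(m) <- dimnames(tensor)[1:2]
  m
}

#' Kruskal-Wallis emotion-sensitivity map per channel and band
#'
#' For every (channel, band) cell, tests whether the per-trial mean feature
#' differs across the three emotion classes, pooling trials across all
#' experiments (tie-corrected H, chi-square reference with 2 df). Run once
#' without and once with ELBN to quantify how the normalization changes
#' feature sensitivity.
#'
#' @param fds feature dataset.
#' @param tw_length TW length at which features are aggregated before the
#'   per-trial mean (default 2 s; without ELBN the result is independent of
#'   this choice by the conservation property).
#' @param elbn `"off"` or `"paper"`.
#' @param pooling ELBN pooling granularity.
#' @return data.frame per (channel, band): `H`, `p`, `n_per_group` (the
#'   smallest group size), with `feature_type` and `elbn` columns.
#' @export
kw_table <- function(fds, tw_length = 2, elbn = c("off", "paper"),
                     pooling = "all_windows") {
  elbn <- match.arg(elbn)
  tws <- tw_tensors(fds, tw_length)
  if (elbn == "paper") {
    tws <- lapply(tws, function(e) {
      e$tensors <- elbn_normalize_session(e$tensors, pooling = pooling)
      e
    })
  }
  means <- list(); labels <- integer(0)
  for (e in tws) {
    means <- c(means, lapply(e$tensors, trial_mean_features))
    labels <- c(labels, e$labels)
  }
  n_tr <- length(means)
  arr <- array(unlist(means, use.names = FALSE), dim = c(58L, 5L, n_tr))
  g <- factor(labels, levels = c(-1, 0, 1))
  if (min(table(g)) < 2) stop("need at least 2 trials per emotion class")
  bands <- band_scheme()$band
  chans <- retained_channels()
  ft <- attr(fds, "feature_type")
  rows <- list()
  warned <- FALSE
  for (b in 1:5) {
    for (ch in 1:58) {
      v <- arr[ch, b, ]
      if (stats::var(v) == 0) {
        if (!warned) {
          warning("degenerate (all-tied) feature cell(s); p set to 1")
          warned <- TRUE
        }
        H <- 0; p <- 1
      } else {
        kt <- stats::kruskal.test(v, g)
        H <- unname(kt$statistic); p <- kt$p.value
      }
      rows[[length(rows) + 1]] <- data.frame(
        feature_type = if (is.null(ft)) NA_character_ else ft,
        band = bands[b], channel = chans[ch], elbn = elbn,
        H = H, p = p, n_per_group = min(table(g))
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count significant channel-band cells
#'
#' @param table output of [kw_table()] (or several rbind-ed together).
#' @param alpha significance level (default 0.05; no multiplicity
#'   correction, matching the analysis this reproduces).
#' @return data.frame of counts per (feature_type, elbn) present in the
#'   table; zero rows count as zero.
#' @export
significance_count <- function(table, alpha = 0.05) {
  if (nrow(table) == 0)
    return(data.frame(feature_type = character(0), elbn = character(0),
                      n_significant = integer(0)))
  agg <- stats::aggregate(p ~ feature_type + elbn, data = table,
                          FUN = function(p) sum(p <= alpha))
  names(agg)[names(agg) == "p"] <- "n_significant"
  agg
}

#' Wide significance rendering for a channel subset
#'
#' @param table output of [kw_table()].
#' @param channels channel names to show as columns (default the first 18
#'   retained channels).
#' @return matrix of p-values, rows = band, columns = channel.
#' @export
kw_wide <- function(table, channels = retained_channels()[1:18]) {
  bands <- band_scheme()$band
  m <- matrix(NA_real_, length(bands), length(channels),
              dimnames = list(bands, channels))
  sub <- table[table$channel %in% channels, ]
  for (i in seq_len(nrow(sub))) m[sub$band[i], sub$channel[i]] <- sub$p[i]
  m
}
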