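#' Default end-to-end run configuration
#'
#' All defaults follow the published design: the 11 TW lengths, the six
#' classifiers with their printed settings, the 10 fixed split sets, 2-s /
#' 1-s online windows, pooled within-experiment ELBN. The generator scale
#' defaults to the full 15 subjects x 3 sessions; scaled runs shrink
#' `n_subjects` / `n_experiments_per_subject`.
#'
#' @param ... named overrides of top-level keys; `generator` may be a
#'   partial list merged over the generator defaults.
#' @return a `run_config` list.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    generator = list(
      n_subjects = 15, n_experiments_per_subject = 3,
      drift_gain_sd = 0.4, drift_offset_sd = 0.5,
      class_effect_scale = 1
    ),
    feature_type = "psd",
    lds = FALSE,
    lds_qr = 0.01,
    tw_lengths = tw_table()$tw_length,
    elbn = list(enabled = TRUE, pooling = "all_windows", mode = "paper"),
    bagging_estimators = 500,
    online = list(window = 2, step = 1),
    out_dir = "results",
    seed = 1L
  )
  over <- list(...)
  for (nm in names(over)) {
    if (nm %in% c("generator", "elbn", "online") && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else cfg[[nm]] <- over[[nm]]
  }
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  stopifnot(cfg$feature_type %in% c("psd", "de"),
            all(cfg$tw_lengths %in% tw_table()$tw_length),
            cfg$elbn$pooling %in% c("all_windows", "per_window_index"),
            cfg$elbn$mode %in% c("paper", "causal"),
            cfg$online$step <= cfg$online$window)
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Keys override [default_run_config()] defaults.
#'
#' @param path YAML file.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(default_run_config, yaml::read_yaml(path))
}

#' Hash of a run configuration
#'
#' MD5 of the deparsed configuration; recorded in every output file so a
#' result can be traced to the exact settings that produced it.
#'
#' @param cfg a run config (any R list).
#' @return character MD5 hash.
#' @export
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg), f)
  unname(tools::md5sum(f))
}

# CSV with a provenance header line ("# config_hash: ...").
write_output_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Generates a synthetic feature dataset, evaluates the offline classifier
#' grid without and (if enabled) with ELBN, contrasts the two, runs
#' sliding-window online recognition, computes the Kruskal-Wallis
#' sensitivity maps, and writes all tables plus a JSON manifest to
#' `cfg$out_dir`.
#'
#' @param cfg a run config from [default_run_config()] /
#'   [read_run_config()].
#' @return the manifest list, invisibly. Outputs written:
#'   `accuracy_no_elbn.csv`, `accuracy_elbn.csv` (if enabled),
#'   `elbn_improvement.csv`, `online_summary.csv`, `online_accuracy.csv`,
#'   `kw_significance.csv`, `kw_counts.csv`, `manifest.json`.
#' @export
run_pipeline <- function(cfg) {
  validate_run_config(cfg)
  hash <- config_hash(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  tick <- function(nm) {
    timings[[nm]] <<- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    t0 <<- Sys.time()
  }

  gen <- cfg$generator
  gcfg <- generator_config(
    n_subjects = gen$n_subjects,
    n_experiments_per_subject = gen$n_experiments_per_subject,
    class_band_effects = default_class_effects(gen$class_effect_scale),
    drift_gain_sd = gen$drift_gain_sd,
    drift_offset_sd = gen$drift_offset_sd,
    seed = cfg$seed
  )
  fds <- simulate_feature_dataset(gcfg, feature_type = cfg$feature_type,
                                  lds = cfg$lds, lds_qr = cfg$lds_qr)
  tick("generate")

  specs <- classifier_specs(bagging_estimators = cfg$bagging_estimators)
  splits <- split_sets(quiet = TRUE)
  res_off <- evaluate_grid(fds, tw_lengths = cfg$tw_lengths, specs = specs,
                           splits = splits, elbn = "off")
  sum_off <- summarize_accuracy(res_off)
  write_output_csv(sum_off, file.path(cfg$out_dir, "accuracy_no_elbn.csv"), hash)
  tick("evaluate_no_elbn")

  files <- c("accuracy_no_elbn.csv")
  if (isTRUE(cfg$elbn$enabled)) {
    res_on <- evaluate_grid(fds, tw_lengths = cfg$tw_lengths, specs = specs,
                            splits = splits, elbn = cfg$elbn$mode,
                            pooling = cfg$elbn$pooling)
    sum_on <- summarize_accuracy(res_on)
    write_output_csv(sum_on, file.path(cfg$out_dir, "accuracy_elbn.csv"), hash)
    imp <- elbn_contrast(sum_off, sum_on)
    write_output_csv(imp, file.path(cfg$out_dir, "elbn_improvement.csv"), hash)
    files <- c(files, "accuracy_elbn.csv", "elbn_improvement.csv")
    tick("evaluate_elbn")
  }

  onl <- run_online(fds, splits = splits, window = cfg$online$window,
                    step = cfg$online$step,
                    elbn = if (isTRUE(cfg$elbn$enabled)) cfg$elbn$mode else "off",
                    pooling = cfg$elbn$pooling)
  write_output_csv(onl$summary, file.path(cfg$out_dir, "online_summary.csv"), hash)
  write_output_csv(onl$accuracy, file.path(cfg$out_dir, "online_accuracy.csv"), hash)
  files <- c(files, "online_summary.csv", "online_accuracy.csv")
  tick("online")

  kw <- rbind(kw_table(fds, elbn = "off"),
              kw_table(fds, elbn = "paper", pooling = cfg$elbn$pooling))
  write_output_csv(kw, file.path(cfg$out_dir, "kw_significance.csv"), hash)
  counts <- significance_count(kw)
  write_output_csv(counts, file.path(cfg$out_dir, "kw_counts.csv"), hash)
  files <- c(files, "kw_significance.csv", "kw_counts.csv")
  tick("stats")

  manifest <- list(
    config_hash = hash, seed = cfg$seed, config = cfg,
    package_version = as.character(utils::packageVersion("eegtw")),
    r_version = R.version.string,
    timings_s = timings, outputs = files,
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
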