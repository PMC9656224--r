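#' Declarative pipeline configuration
#'
#' A single named list drives the command-level pipeline. Defaults
#' reproduce the published analysis settings wherever one is stated:
#' 4 s windows with a 2 s step, the Emotiv 14-channel EEG subset, 8
#' histogram bins for MI, ApEn with m = 2 and r = 0.2 sd, the GA
#' parameter block of [ga_config()], and the [cnn_architecture()]
#' defaults. Values given in `overrides` (e.g. parsed from a JSON config
#' file) replace defaults field by field; CLI flags take precedence over
#' the file.
#'
#' @param overrides Named list of overrides (possibly nested for `ga` and
#'   `cnn`).
#' @return List of class `emo_pipeline_config`.
#' @export
pipeline_config <- function(overrides = list()) {
  base <- list(window_s = 4, step_s = 2, channels = NULL, bins = 8L,
               apen_m = 2L, apen_r_factor = 0.2,
               ga = unclass(ga_config()), cnn = unclass(cnn_architecture()),
               learner = "svm", protocol = "subject_dependent",
               dimension = "valence", use_ga = FALSE, seed = 0L,
               data_dir = NULL, features_path = NULL, report_path = NULL)
  cfg <- utils::modifyList(base, overrides)
  stopifnot(cfg$window_s > 0, cfg$step_s > 0, cfg$bins >= 2L,
            cfg$learner %in% c("svm", "rf", "xgb", "cnn"),
            cfg$protocol %in% c("subject_dependent", "subject_independent"),
            cfg$dimension %in% c("valence", "arousal"))
  structure(cfg, class = "emo_pipeline_config")
}

#' Hash of a pipeline configuration (for run logging)
#'
#' @param cfg A [pipeline_config()].
#' @return Character scalar.
#' @export
config_hash <- function(cfg) {
  json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                           null = "null")
  # small deterministic polynomial hash; no digest dependency
  bytes <- utf8ToInt(as.character(json))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

log_msg <- function(...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(...)))
}

#' Generate a synthetic dataset on disk
#'
#' @param spec_file JSON file of [generator_spec()] fields, or `NULL` for
#'   defaults.
#' @param out_dir Output directory.
#' @param seed Optional seed override.
#' @return Written file paths, invisibly.
#' @export
cmd_generate <- function(spec_file = NULL, out_dir, seed = NULL) {
  fields <- if (is.null(spec_file)) list()
            else jsonlite::read_json(spec_file, simplifyVector = TRUE)
  if (!is.null(seed)) fields$seed <- as.integer(seed)
  spec <- do.call(generator_spec, fields)
  t0 <- Sys.time()
  paths <- write_dataset(spec, out_dir)
  log_msg("generate: %d subjects -> %s (%.1f s)", length(paths), out_dir,
          as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(paths)
}

#' Extract the feature table of a dataset directory
#'
#' Reads every `*.h5` recording under `cfg$data_dir`, extracts the fused
#' per-window features and writes them as CSV to `cfg$features_path`.
#'
#' @param cfg A [pipeline_config()] with `data_dir` and `features_path`
#'   set.
#' @return The feature data.frame, invisibly.
#' @export
cmd_extract <- function(cfg) {
  stopifnot(!is.null(cfg$data_dir), !is.null(cfg$features_path))
  files <- sort(list.files(cfg$data_dir, pattern = "\\.h5$",
                           full.names = TRUE))
  if (!length(files)) stop("no recordings (*.h5) found in ", cfg$data_dir)
  t0 <- Sys.time()
  recs <- lapply(files, read_recording)
  channels <- cfg$channels
  if (!is.null(channels)) channels <- as.character(channels)
  feats <- extract_features(recs, window_s = cfg$window_s,
                            step_s = cfg$step_s, channels = channels,
                            bins = cfg$bins)
  write.csv(feats, cfg$features_path, row.names = FALSE)
  log_msg("extract [cfg %s]: %d windows x %d columns -> %s (%.1f s)",
          config_hash(cfg), nrow(feats), ncol(feats), cfg$features_path,
          as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(feats)
}

#' Run an evaluation protocol on an extracted feature table
#'
#' @param cfg A [pipeline_config()] with `features_path` (CSV from
#'   [cmd_extract()]) and optionally `report_path` set.
#' @return The `emo_report`, invisibly.
#' @export
cmd_evaluate <- function(cfg) {
  stopifnot(!is.null(cfg$features_path))
  feats <- read.csv(cfg$features_path, check.names = FALSE)
  ga_cfg <- list(cfg = do.call(ga_config, cfg$ga), classifier_kind = "svm")
  learner_config <- if (cfg$learner == "cnn") cfg$cnn[
    setdiff(names(cfg$cnn), "seed")] else list()
  t0 <- Sys.time()
  report <- if (cfg$protocol == "subject_dependent")
    subject_dependent_eval(feats, cfg$dimension, cfg$learner,
                           use_ga = cfg$use_ga, ga_cfg = ga_cfg,
                           seed = cfg$seed, learner_config = learner_config)
  else
    loocv_eval(feats, cfg$dimension, cfg$learner, use_ga = cfg$use_ga,
               ga_cfg = ga_cfg, seed = cfg$seed,
               learner_config = learner_config)
  if (!is.null(cfg$report_path)) write_report_json(report, cfg$report_path)
  log_msg("evaluate [cfg %s]: %s %s %s -> %.4f +/- %.4f (%.1f s)",
          config_hash(cfg), report$protocol, report$dimension,
          report$learner, report$mean,
          if (is.na(report$sd)) 0 else report$sd,
          as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(report)
}
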