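#' @name evaluation-protocols
#' @title Subject-dependent and subject-independent evaluation
#' @description
#' Two protocols are provided. In the subject-dependent protocol each
#' subject's windows are split 85/15 (stratified on the binary label) and
#' a subject-specific model is trained and tested on that subject alone.
#' In the subject-independent protocol a leave-one-subject-out
#' cross-validation holds out each subject in turn: feature selection and
#' model fitting see only the pooled training subjects (the GA's inner
#' 85/15 fitness split is drawn from those rows), and accuracy is measured
#' on every window of the held-out subject. Both report per-unit
#' accuracies with their mean and standard deviation.
NULL

new_report <- function(protocol, dimension, learner, use_ga, per_unit,
                       fingerprint, config) {
  structure(list(protocol = protocol, dimension = dimension,
                 learner = learner, use_ga = use_ga,
                 per_unit = per_unit,
                 mean = mean(per_unit), sd = sd(per_unit),
                 fingerprint = fingerprint, config = config),
            class = "emo_report")
}

#' @export
print.emo_report <- function(x, ...) {
  cat(sprintf("<emo_report> %s / %s / %s%s: accuracy %.4f +/- %.4f over %d units\n",
              x$protocol, x$dimension, x$learner,
              if (x$use_ga) " + GA" else "", x$mean,
              if (is.na(x$sd)) 0 else x$sd, length(x$per_unit)))
  invisible(x)
}

fit_and_score <- function(X, y, train_idx, test_idx, learner, use_ga,
                          ga_cfg, seed, learner_config, unit) {
  ytr <- droplevels(factor(y[train_idx], levels = c("low", "high")))
  if (nlevels(ytr) < 2L)
    stop("training set for unit '", unit, "' contains a single class")
  mask <- rep(TRUE, ncol(X))
  sel <- NULL
  if (use_ga) {
    sel <- ga_select(X[train_idx, , drop = FALSE], y[train_idx],
                     classifier_kind = ga_cfg$classifier_kind %||% "svm",
                     cfg = ga_cfg$cfg %||% ga_config(seed = seed))
    mask <- sel$mask
  }
  model <- train_classifier(learner, X[train_idx, mask, drop = FALSE],
                            y[train_idx], seed = seed,
                            config = learner_config)
  pred <- predict(model, X[test_idx, mask, drop = FALSE])
  list(acc = accuracy(pred, y[test_idx]), selection = sel,
       fingerprint = list(train = train_idx, test = test_idx))
}

#' Subject-dependent evaluation (per-subject 85/15 split)
#'
#' @param features Feature table from [extract_features()].
#' @param dimension `"valence"` or `"arousal"`.
#' @param learner `"svm"`, `"rf"`, `"xgb"` or `"cnn"`.
#' @param use_ga Run GA feature selection on each subject's training
#'   portion first.
#' @param ga_cfg Optional list with elements `cfg` (a [ga_config()]) and
#'   `classifier_kind` for the GA fitness.
#' @param test_frac Held-out fraction (default 0.15).
#' @param group_by_trial If `TRUE`, all windows of a trial go to the same
#'   side of the split (guards against the optimistic bias of windows from
#'   one trial appearing on both sides; default `FALSE`, the literal
#'   windows-level protocol).
#' @param seed Seed for the split and the learner.
#' @param learner_config Extra learner config.
#' @return An `emo_report` with one accuracy per retained subject.
#'   Subjects whose windows carry a single class are excluded with a
#'   warning.
#' @export
subject_dependent_eval <- function(features, dimension = "valence",
                                   learner = "svm", use_ga = FALSE,
                                   ga_cfg = NULL, test_frac = 0.15,
                                   group_by_trial = FALSE, seed = 0L,
                                   learner_config = list()) {
  fm <- feature_matrix(features, dimension)
  subjects <- unique(fm$subject)
  per <- c(); fingerprints <- list()
  for (s in subjects) {
    rows <- which(fm$subject == s)
    ys <- fm$y[rows]
    if (length(unique(as.character(ys))) < 2L) {
      warning("subject '", s, "' has a single ", dimension,
              " class; excluded from the subject-dependent report")
      next
    }
    set.seed(seed + match(s, subjects))
    if (group_by_trial) {
      trials <- fm$trial[rows]
      tlab <- vapply(split(as.character(ys), trials),
                     function(v) v[1L], "")
      t_test <- names(tlab)[stratified_holdout(factor(tlab), test_frac)]
      test_local <- which(trials %in% t_test)
    } else {
      test_local <- stratified_holdout(ys, test_frac)
    }
    train_idx <- rows[-test_local]
    test_idx <- rows[test_local]
    res <- fit_and_score(fm$X, fm$y, train_idx, test_idx, learner, use_ga,
                         ga_cfg, seed + match(s, subjects), learner_config,
                         unit = s)
    per[s] <- res$acc
    fingerprints[[s]] <- res$fingerprint
  }
  if (!length(per)) stop("no subject with both classes present")
  new_report("subject_dependent", dimension, learner, use_ga, per,
             fingerprints,
             list(test_frac = test_frac, seed = seed,
                  group_by_trial = group_by_trial))
}

#' Leave-one-subject-out evaluation (subject-independent)
#'
#' @inheritParams subject_dependent_eval
#' @return An `emo_report` with one accuracy per held-out subject.
#' @export
loocv_eval <- function(features, dimension = "valence", learner = "svm",
                       use_ga = FALSE, ga_cfg = NULL, seed = 0L,
                       learner_config = list()) {
  fm <- feature_matrix(features, dimension)
  subjects <- unique(fm$subject)
  if (length(subjects) < 2L)
    stop("leave-one-subject-out needs at least 2 subjects, got ",
         length(subjects))
  per <- c(); fingerprints <- list()
  for (s in subjects) {
    test_idx <- which(fm$subject == s)
    train_idx <- which(fm$subject != s)
    res <- fit_and_score(fm$X, fm$y, train_idx, test_idx, learner, use_ga,
                         ga_cfg, seed, learner_config,
                         unit = paste0("fold:", s))
    per[s] <- res$acc
    fingerprints[[s]] <- res$fingerprint
  }
  new_report("subject_independent", dimension, learner, use_ga, per,
             fingerprints, list(seed = seed))
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `emo_report`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(protocol = report$protocol, dimension = report$dimension,
         learner = report$learner, use_ga = report$use_ga,
         per_unit = as.list(report$per_unit), mean = report$mean,
         sd = report$sd, config = report$config),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
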