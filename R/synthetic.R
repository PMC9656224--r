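#' Specification of a synthetic multichannel dataset
#'
#' Describes a dataset shaped like a preprocessed affective-physiology
#' study: subjects x trials x (EEG + peripheral) channels x samples, with
#' per-trial valence/arousal ratings. A latent per-trial emotion class
#' drives both the ratings and planted physiological structure:
#'
#' * EEG: a designated channel subset shares a band-limited latent
#'   oscillation; its mixing weight is `0.1` for the low class and
#'   `0.1 + coupling_effect` for the high class, so mutual-information
#'   connectivity (and therefore the graph features) differs between
#'   classes with strength controlled by `coupling_effect`.
#' * Peripheral: autocorrelated noise whose mean shifts by
#'   `peripheral_effect` standard deviations between classes (and whose
#'   scale grows mildly with the class), so windowed statistics are
#'   informative.
#'
#' `mechanism_mode = "shared"` uses the same effect directions for every
#' subject (a population-level mechanism, learnable across subjects);
#' `"idiosyncratic"` randomizes the directions per subject, so
#' subject-specific models work but cross-subject transfer fails.
#'
#' @param n_subjects,n_trials Counts (defaults 4 and 20).
#' @param trial_length_s Trial duration in seconds (default 60, the
#'   one-minute stimulus convention).
#' @param rate_hz Sampling rate (default 128).
#' @param n_eeg_channels,n_peripheral_channels Channel counts (defaults 14
#'   and 8; 14 gets the Emotiv montage labels, 32 the standard research
#'   montage, 8 peripheral the standard sensor names).
#' @param coupling_effect Difference in latent-source mixing weight
#'   between classes (default 0.7, i.e. 0.8 vs 0.1).
#' @param peripheral_effect Between-class mean shift of peripheral
#'   channels in units of their sd (default 2).
#' @param mechanism_mode `"shared"` or `"idiosyncratic"`.
#' @param label_rule List: `p_high` (default 0.5) and the rating ranges
#'   `low_range` (default c(1, 4)) / `high_range` (default c(5, 9)); the
#'   ranges must stay inside \[1, 9\] and on their side of 4.5.
#' @param n_coupled Size of the designated coupled EEG subset (default 4).
#' @param seed Seed (default 0).
#' @return List of class `emo_generator_spec`.
#' @export
generator_spec <- function(n_subjects = 4L, n_trials = 20L,
                           trial_length_s = 60, rate_hz = 128,
                           n_eeg_channels = 14L, n_peripheral_channels = 8L,
                           coupling_effect = 0.7, peripheral_effect = 2,
                           mechanism_mode = c("shared", "idiosyncratic"),
                           label_rule = list(), n_coupled = 4L, seed = 0L) {
  mechanism_mode <- match.arg(mechanism_mode)
  lr <- utils::modifyList(list(p_high = 0.5, low_range = c(1, 4),
                               high_range = c(5, 9)), label_rule)
  stopifnot(n_subjects >= 1L, n_trials >= 1L, trial_length_s > 0,
            rate_hz > 0, n_eeg_channels >= 2L, n_peripheral_channels >= 1L,
            coupling_effect >= 0, peripheral_effect >= 0,
            n_coupled >= 2L, n_coupled <= n_eeg_channels)
  if (abs(trial_length_s * rate_hz - round(trial_length_s * rate_hz)) > 1e-9)
    stop("trial_length_s * rate_hz must be an integer sample count")
  if (lr$low_range[1L] < 1 || lr$low_range[2L] > 4.5 ||
      lr$high_range[1L] <= 4.5 || lr$high_range[2L] > 9)
    stop("label_rule ranges must lie within [1, 9] and respect the 4.5 cut")
  if (0.1 + coupling_effect > 0.98)
    stop("coupling_effect too large: mixing weight would exceed 1")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials),
                 trial_length_s = trial_length_s, rate_hz = rate_hz,
                 n_eeg_channels = as.integer(n_eeg_channels),
                 n_peripheral_channels = as.integer(n_peripheral_channels),
                 coupling_effect = coupling_effect,
                 peripheral_effect = peripheral_effect,
                 mechanism_mode = mechanism_mode, label_rule = lr,
                 n_coupled = as.integer(n_coupled), seed = as.integer(seed)),
            class = "emo_generator_spec")
}

eeg_labels_for <- function(n) {
  if (n == 14L) EMOTIV_14
  else if (n == 32L) DEAP_EEG_32
  else paste0("EEG", seq_len(n))
}

peripheral_labels_for <- function(n) {
  if (n == 8L) DEAP_PERIPHERAL_8 else paste0("P", seq_len(n))
}

# Unit-sd band-limited oscillation: a few sinusoids with random
# frequencies and phases, so the signal is autocorrelated like real EEG.
oscillation <- function(n, rate_hz, n_components = 3L) {
  t <- (seq_len(n) - 1L) / rate_hz
  fmax <- min(30, rate_hz / 4)
  x <- rowSums(vapply(seq_len(n_components), function(k)
    sin(2 * pi * runif(1, 2, fmax) * t + runif(1, 0, 2 * pi)),
    numeric(n)))
  s <- pop_sd(x)
  if (s == 0) x else x / s
}

ar1_noise <- function(n, phi = 0.9) {
  x <- as.numeric(stats::filter(rnorm(n), phi, method = "recursive"))
  x / sqrt(1 / (1 - phi^2))  # unit marginal sd
}

#' Generate a synthetic dataset
#'
#' @param spec A [generator_spec()].
#' @return List of `emo_recording` objects, one per subject. Fully
#'   deterministic given `spec$seed`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "emo_generator_spec"))
  set.seed(spec$seed)
  n <- as.integer(round(spec$trial_length_s * spec$rate_hz))
  eeg_ch <- eeg_labels_for(spec$n_eeg_channels)
  per_ch <- peripheral_labels_for(spec$n_peripheral_channels)
  coupled <- seq_len(spec$n_coupled)
  lr <- spec$label_rule
  lapply(seq_len(spec$n_subjects), function(si) {
    if (spec$mechanism_mode == "shared") {
      per_dir <- 1
      swap_coupling <- FALSE
    } else {
      per_dir <- sample(c(-1, 1), 1L)
      swap_coupling <- runif(1) < 0.5
    }
    trials <- lapply(seq_len(spec$n_trials), function(ti) {
      high <- runif(1) < lr$p_high
      valence <- if (high) runif(1, lr$high_range[1L], lr$high_range[2L])
                 else runif(1, lr$low_range[1L], lr$low_range[2L])
      arousal <- if (high) runif(1, lr$high_range[1L], lr$high_range[2L])
                 else runif(1, lr$low_range[1L], lr$low_range[2L])
      strong <- xor(high, swap_coupling)
      alpha <- 0.1 + if (strong) spec$coupling_effect else 0
      z <- oscillation(n, spec$rate_hz)
      eeg <- matrix(0, spec$n_eeg_channels, n,
                    dimnames = list(eeg_ch, NULL))
      for (ci in seq_len(spec$n_eeg_channels)) {
        own <- sqrt(0.5) * oscillation(n, spec$rate_hz) +
               sqrt(0.5) * rnorm(n)
        eeg[ci, ] <- if (ci %in% coupled)
          alpha * z + sqrt(1 - alpha^2) * own else own
      }
      shift <- per_dir * spec$peripheral_effect * (if (high) 0.5 else -0.5)
      scale <- if (high) 1 + 0.25 * spec$peripheral_effect else 1
      per <- matrix(0, spec$n_peripheral_channels, n,
                    dimnames = list(per_ch, NULL))
      for (ci in seq_len(spec$n_peripheral_channels))
        per[ci, ] <- shift + scale * ar1_noise(n)
      new_trial(sprintf("trial%02d", ti), eeg, per, valence, arousal)
    })
    new_recording(sprintf("sub%02d", si), trials, spec$rate_hz)
  })
}

#' Ground truth of the planted structure
#'
#' @param spec A [generator_spec()].
#' @return List: `coupled_channels` (labels of the designated EEG subset),
#'   `coupled_pairs` (2-column matrix of all unordered pairs within it),
#'   `peripheral_channels`, and `informative_stats` (the peripheral
#'   statistics shifted by the planted mean/scale effect).
#' @export
ground_truth <- function(spec) {
  stopifnot(inherits(spec, "emo_generator_spec"))
  ch <- eeg_labels_for(spec$n_eeg_channels)[seq_len(spec$n_coupled)]
  pairs <- t(utils::combn(ch, 2L))
  colnames(pairs) <- c("a", "b")
  list(coupled_channels = ch, coupled_pairs = pairs,
       peripheral_channels = peripheral_labels_for(spec$n_peripheral_channels),
       informative_stats = c("mean", "variance", "std", "max", "min",
                             "q25", "q50", "q75"))
}

#' Write a dataset plus its ground-truth sidecar
#'
#' @param spec A [generator_spec()].
#' @param dir Output directory (created if needed); one HDF5 file per
#'   subject plus `ground_truth.json`.
#' @return Character vector of written recording paths, invisibly.
#' @export
write_dataset <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- generate_dataset(spec)
  paths <- vapply(recs, function(rec) {
    p <- file.path(dir, paste0(rec$subject_id, ".h5"))
    write_recording(rec, p)
    p
  }, "")
  gt <- ground_truth(spec)
  jsonlite::write_json(
    list(coupled_channels = gt$coupled_channels,
         coupled_pairs = apply(gt$coupled_pairs, 1L, paste, collapse = "-"),
         peripheral_channels = gt$peripheral_channels,
         informative_stats = gt$informative_stats,
         spec = unclass(spec)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
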