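#' The 14 EEG channels of the Emotiv epoc+ headset
#'
#' Default EEG channel subset used throughout the pipeline, named in the
#' international 10-20 system. These are the 14 positions available on the
#' consumer-grade Emotiv epoc+ headset, a common target montage when a
#' method is meant to transfer from research-grade caps to wearables.
#'
#' @format Character vector of length 14.
#' @export
EMOTIV_14 <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
               "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")

#' Construct a single trial
#'
#' A trial holds the multichannel signals recorded while one stimulus
#' (e.g. a one-minute video) was presented, together with the subject's
#' self-reported valence and arousal ratings on the 1-9 scale.
#'
#' @param trial_id Character scalar identifying the trial within its
#'   recording.
#' @param eeg Numeric matrix, EEG channels x samples, with rownames giving
#'   the channel labels. At least 2 channels.
#' @param peripheral Numeric matrix, peripheral channels x samples, with
#'   rownames giving the channel labels. Must have the same number of
#'   samples as `eeg`.
#' @param valence,arousal Numeric ratings in \[1, 9\].
#' @return An object of class `emo_trial`.
#' @export
new_trial <- function(trial_id, eeg, peripheral, valence, arousal) {
  stopifnot(is.character(trial_id), length(trial_id) == 1L)
  if (!is.matrix(eeg) || !is.numeric(eeg))
    stop("`eeg` must be a numeric matrix (channels x samples)")
  if (!is.matrix(peripheral) || !is.numeric(peripheral))
    stop("`peripheral` must be a numeric matrix (channels x samples)")
  if (is.null(rownames(eeg)) || is.null(rownames(peripheral)))
    stop("signal matrices need rownames giving the channel labels")
  if (nrow(eeg) < 2L)
    stop("a trial needs at least 2 EEG channels, got ", nrow(eeg))
  if (ncol(eeg) != ncol(peripheral))
    stop("eeg and peripheral must have equal sample counts (",
         ncol(eeg), " vs ", ncol(peripheral), ")")
  check_rating(valence, "valence")
  check_rating(arousal, "arousal")
  structure(list(trial_id = trial_id, eeg = eeg, peripheral = peripheral,
                 valence = as.numeric(valence), arousal = as.numeric(arousal)),
            class = "emo_trial")
}

check_rating <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x > 9)
    stop("`", what, "` must be a single rating in [1, 9], got ",
         deparse(substitute(x)), " = ", format(x))
  invisible(x)
}

#' Construct a recording (one subject's trials)
#'
#' @param subject_id Character scalar.
#' @param trials List of [new_trial()] objects. All trials must share the
#'   same EEG and peripheral channel sets.
#' @param rate_hz Common sampling rate in samples/second (positive).
#' @return An object of class `emo_recording`.
#' @export
new_recording <- function(subject_id, trials, rate_hz) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("`rate_hz` must be a single positive number")
  if (!length(trials) || !all(vapply(trials, inherits, TRUE, "emo_trial")))
    stop("`trials` must be a non-empty list of emo_trial objects")
  eeg_ch <- rownames(trials[[1L]]$eeg)
  per_ch <- rownames(trials[[1L]]$peripheral)
  for (tr in trials) {
    if (!identical(rownames(tr$eeg), eeg_ch) ||
        !identical(rownames(tr$peripheral), per_ch))
      stop("all trials of a recording must share identical channel sets; ",
           "trial '", tr$trial_id, "' differs")
  }
  structure(list(subject_id = subject_id, trials = trials,
                 rate_hz = as.numeric(rate_hz)),
            class = "emo_recording")
}

#' @export
print.emo_recording <- function(x, ...) {
  tr <- x$trials[[1L]]
  cat(sprintf(
    "<emo_recording> subject %s: %d trials, %d EEG + %d peripheral channels @ %g Hz\n",
    x$subject_id, length(x$trials), nrow(tr$eeg), nrow(tr$peripheral),
    x$rate_hz))
  invisible(x)
}

#' @export
print.emo_trial <- function(x, ...) {
  cat(sprintf(
    "<emo_trial> %s: %d EEG + %d peripheral channels, %d samples, valence %.2f, arousal %.2f\n",
    x$trial_id, nrow(x$eeg), nrow(x$peripheral), ncol(x$eeg),
    x$valence, x$arousal))
  invisible(x)
}

#' Dichotomize a 1-9 affect rating into low/high
#'
#' Ratings at or below the scale midpoint band (<= 4.5) map to `"low"`,
#' everything above to `"high"`. This is the usual binarization of the
#' continuous valence/arousal self-assessment scale.
#'
#' @param rating Numeric vector of ratings, each in \[1, 9\].
#' @return Factor with ordered levels `low < high`, same length as `rating`.
#' @examples
#' dichotomize(c(1, 4.5, 4.6, 9))
#' @export
dichotomize <- function(rating) {
  if (!is.numeric(rating) || anyNA(rating) ||
      any(rating < 1) || any(rating > 9))
    stop("ratings must be numeric values in [1, 9]")
  factor(ifelse(rating <= 4.5, "low", "high"),
         levels = c("low", "high"), ordered = TRUE)
}

#' Restrict a trial to a subset of EEG channels
#'
#' @param trial An `emo_trial`.
#' @param wanted Character vector of EEG channel labels; defaults to the
#'   Emotiv epoc+ 14-channel montage ([EMOTIV_14]). Output channel order
#'   follows `wanted`.
#' @return The trial with its EEG matrix restricted (and reordered) to
#'   `wanted`. Peripheral channels are untouched.
#' @export
select_channels <- function(trial, wanted = EMOTIV_14) {
  stopifnot(inherits(trial, "emo_trial"), is.character(wanted),
            length(wanted) >= 2L)
  missing <- setdiff(wanted, rownames(trial$eeg))
  if (length(missing))
    stop("unknown EEG channel label(s): ", paste(missing, collapse = ", "))
  trial$eeg <- trial$eeg[wanted, , drop = FALSE]
  trial
}

#' Apply an EEG channel subset to every trial of a recording
#'
#' @inheritParams select_channels
#' @param recording An `emo_recording`.
#' @return The recording with every trial's EEG restricted to `wanted`.
#' @export
select_channels_recording <- function(recording, wanted = EMOTIV_14) {
  stopifnot(inherits(recording, "emo_recording"))
  recording$trials <- lapply(recording$trials, select_channels, wanted = wanted)
  recording
}

#' Slice a trial into sliding analysis windows
#'
#' Left-aligned fixed-duration windows; the last window is the last one
#' that fits entirely inside the trial, so a trailing remainder shorter
#' than `window_s` is discarded. Each window inherits the trial's valence
#' and arousal ratings.
#'
#' @param trial An `emo_trial`.
#' @param rate_hz Sampling rate in Hz.
#' @param window_s Window length in seconds (default 4).
#' @param step_s Step between window starts in seconds (default 2).
#' @param subject_id Optional subject id recorded in each window's source.
#' @return List of `emo_window` objects, each with fields `source`
#'   (subject_id, trial_id), `start_s`, `length_s`, `eeg`, `peripheral`,
#'   `valence`, `arousal`.
#' @export
slide_windows <- function(trial, rate_hz, window_s = 4, step_s = 2,
                          subject_id = NA_character_) {
  stopifnot(inherits(trial, "emo_trial"))
  wlen <- window_s * rate_hz
  slen <- step_s * rate_hz
  if (wlen <= 0 || abs(wlen - round(wlen)) > 1e-9)
    stop("window_s * rate_hz must be a positive integer sample count")
  if (slen <= 0 || abs(slen - round(slen)) > 1e-9)
    stop("step_s * rate_hz must be a positive integer sample count")
  wlen <- as.integer(round(wlen)); slen <- as.integer(round(slen))
  n <- ncol(trial$eeg)
  if (n < wlen)
    stop("trial '", trial$trial_id, "' is shorter (", n / rate_hz,
         " s) than one window (", window_s, " s)")
  starts <- seq.int(0L, n - wlen, by = slen)
  lapply(starts, function(s0) {
    idx <- (s0 + 1L):(s0 + wlen)
    structure(list(
      source = c(subject_id = subject_id, trial_id = trial$trial_id),
      start_s = s0 / rate_hz, length_s = window_s,
      eeg = trial$eeg[, idx, drop = FALSE],
      peripheral = trial$peripheral[, idx, drop = FALSE],
      valence = trial$valence, arousal = trial$arousal),
      class = "emo_window")
  })
}

#' Number of sliding windows that fit in a trial
#'
#' `floor((T_s - window_s) / step_s) + 1` for a trial of duration `T_s`
#' seconds (0 windows never occurs: shorter-than-window trials error in
#' [slide_windows()]).
#'
#' @param trial_s,window_s,step_s Durations in seconds.
#' @return Integer window count.
#' @export
n_windows <- function(trial_s, window_s = 4, step_s = 2) {
  if (trial_s < window_s) stop("trial shorter than one window")
  as.integer(floor((trial_s - window_s) / step_s) + 1)
}
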