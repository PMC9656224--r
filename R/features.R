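#' Fuse peripheral and graph feature blocks for one window
#'
#' Feature-level fusion is plain concatenation: the peripheral statistical
#' block first, the graph-measure block second. Peripheral names are
#' `<channel>__<statistic>` and graph names `<measure>` or
#' `<measure>__<channel>`, so collisions cannot occur.
#'
#' @param peripheral Named numeric vector from
#'   [peripheral_feature_vector()] (may be length 0 to use graph features
#'   alone).
#' @param graph Named numeric vector from [graph_feature_block()] (may be
#'   length 0 to use peripheral features alone).
#' @return Named numeric vector, peripheral block then graph block.
#' @export
concatenate_features <- function(peripheral, graph) {
  out <- c(peripheral, graph)
  if (anyDuplicated(names(out)))
    stop("duplicate feature names after concatenation")
  out
}

#' Extract the fused feature vector of one window
#'
#' @param window An `emo_window`.
#' @param bins MI histogram bins (default 8).
#' @return Named numeric vector: `12 * C_p` peripheral features followed by
#'   `5 + 4 * C_e` graph features.
#' @export
window_feature_vector <- function(window, bins = 8L) {
  concatenate_features(peripheral_feature_vector(window),
                       graph_feature_block(connectivity_matrix(window, bins)))
}

#' Extract the per-window feature table of a dataset
#'
#' Slides windows over every trial of every recording and computes the
#' fused feature vector for each. One row per window; metadata columns
#' `subject_id`, `trial_id`, `start_s`, `valence`, `arousal` are followed
#' by the named features (`12 C_p + 5 + 4 C_e` columns).
#'
#' @param recordings List of `emo_recording` objects (or a single one).
#' @param window_s,step_s Window length and step in seconds (defaults 4
#'   and 2).
#' @param channels EEG channel subset applied before connectivity analysis;
#'   `NULL` keeps all channels. Defaults to `NULL` so generated data with
#'   arbitrary montages work; pass [EMOTIV_14] for 32-channel recordings.
#' @param bins MI histogram bins.
#' @return A data.frame.
#' @export
extract_features <- function(recordings, window_s = 4, step_s = 2,
                             channels = NULL, bins = 8L) {
  if (inherits(recordings, "emo_recording")) recordings <- list(recordings)
  rows <- list()
  for (rec in recordings) {
    for (tr in rec$trials) {
      if (!is.null(channels)) tr <- select_channels(tr, channels)
      wins <- slide_windows(tr, rec$rate_hz, window_s, step_s,
                            subject_id = rec$subject_id)
      for (w in wins) {
        feats <- window_feature_vector(w, bins)
        rows[[length(rows) + 1L]] <- c(
          list(subject_id = rec$subject_id, trial_id = tr$trial_id,
               start_s = w$start_s, valence = w$valence,
               arousal = w$arousal), as.list(feats))
      }
    }
  }
  if (!length(rows)) stop("no windows extracted: empty input")
  nm <- names(rows[[1L]])
  df <- as.data.frame(lapply(nm, function(cn)
    unlist(lapply(rows, `[[`, cn), use.names = FALSE)),
    col.names = nm, check.names = FALSE, stringsAsFactors = FALSE)
  df
}

METADATA_COLS <- c("subject_id", "trial_id", "start_s", "valence", "arousal")

#' Split a feature table into matrix + labels for one affect dimension
#'
#' @param features Data.frame from [extract_features()].
#' @param dimension `"valence"` or `"arousal"`.
#' @return List with `X` (numeric matrix, windows x features), `y` (factor
#'   low/high from [dichotomize()]), `subject` (character vector),
#'   `trial` (character vector).
#' @export
feature_matrix <- function(features, dimension = c("valence", "arousal")) {
  dimension <- match.arg(dimension)
  fcols <- setdiff(names(features), METADATA_COLS)
  X <- as.matrix(features[, fcols, drop = FALSE])
  if (!all(is.finite(X))) stop("non-finite values in feature matrix")
  list(X = X, y = dichotomize(features[[dimension]]),
       subject = features$subject_id, trial = features$trial_id)
}
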