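#' Write a recording to the native HDF5 layout
#'
#' One file per subject. Layout: group `/trials/<trial_id>` holds float64
#' datasets `eeg` (channels x samples) and `peripheral` (channels x
#' samples) with string-array attributes `eeg_channels` /
#' `peripheral_channels` and scalar attributes `valence` / `arousal`; the
#' root carries `subject_id`, `rate_hz` and `trial_order` (so trial order
#' survives HDF5's alphabetical group listing).
#'
#' @param recording An `emo_recording`.
#' @param path Output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "emo_recording"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "trials")
  for (tr in recording$trials) {
    grp <- paste0("trials/", tr$trial_id)
    rhdf5::h5createGroup(path, grp)
    rhdf5::h5write(unname(tr$eeg), path, paste0(grp, "/eeg"))
    rhdf5::h5write(unname(tr$peripheral), path, paste0(grp, "/peripheral"))
  }
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(recording$subject_id, fid, "subject_id")
  rhdf5::h5writeAttribute(recording$rate_hz, fid, "rate_hz")
  rhdf5::h5writeAttribute(vapply(recording$trials, `[[`, "", "trial_id"),
                          fid, "trial_order")
  for (tr in recording$trials) {
    gid <- rhdf5::H5Gopen(fid, paste0("trials/", tr$trial_id))
    rhdf5::h5writeAttribute(rownames(tr$eeg), gid, "eeg_channels")
    rhdf5::h5writeAttribute(rownames(tr$peripheral), gid, "peripheral_channels")
    rhdf5::h5writeAttribute(tr$valence, gid, "valence")
    rhdf5::h5writeAttribute(tr$arousal, gid, "arousal")
    rhdf5::H5Gclose(gid)
  }
  rhdf5::H5Fclose(fid)
  on.exit()                 # rhdf5 attribute writes can leak handles
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a recording from the native HDF5 layout
#'
#' @param path File written by [write_recording()].
#' @return An `emo_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  root <- rhdf5::h5readAttributes(path, "/")
  for (a in c("subject_id", "rate_hz", "trial_order"))
    if (is.null(root[[a]]))
      stop("malformed recording file: missing root attribute '", a, "'")
  contents <- rhdf5::h5ls(path)
  if (!any(contents$name == "trials" & contents$group == "/"))
    stop("malformed recording file: missing group '/trials'")
  trials <- lapply(as.character(root$trial_order), function(tid) {
    grp <- paste0("trials/", tid)
    at <- rhdf5::h5readAttributes(path, grp)
    for (a in c("eeg_channels", "peripheral_channels", "valence", "arousal"))
      if (is.null(at[[a]]))
        stop("malformed recording file: trial '", tid,
             "' missing attribute '", a, "'")
    eeg <- rhdf5::h5read(path, paste0(grp, "/eeg"))
    per <- rhdf5::h5read(path, paste0(grp, "/peripheral"))
    rownames(eeg) <- as.character(at$eeg_channels)
    rownames(per) <- as.character(at$peripheral_channels)
    new_trial(tid, eeg, per, as.numeric(at$valence), as.numeric(at$arousal))
  })
  rhdf5::h5closeAll()
  new_recording(as.character(root$subject_id), trials,
                as.numeric(root$rate_hz))
}

#' Export per-trial ratings as CSV
#'
#' @param recordings List of `emo_recording` objects (or a single one).
#' @param path Output CSV path with columns
#'   `subject_id,trial_id,valence,arousal`.
#' @return The ratings data.frame, invisibly.
#' @export
write_ratings_csv <- function(recordings, path) {
  if (inherits(recordings, "emo_recording")) recordings <- list(recordings)
  rows <- do.call(rbind, lapply(recordings, function(rec) {
    data.frame(subject_id = rec$subject_id,
               trial_id = vapply(rec$trials, `[[`, "", "trial_id"),
               valence = vapply(rec$trials, `[[`, 0, "valence"),
               arousal = vapply(rec$trials, `[[`, 0, "arousal"))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}

# Standard 32-channel montage of the DEAP recordings (10-20 labels, in the
# dataset's channel order), followed by its 8 peripheral sensors.
DEAP_EEG_32 <- c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5",
                 "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz", "Fp2", "AF4",
                 "Fz", "F4", "F8", "FC6", "FC2", "Cz", "C4", "T8", "CP6",
                 "CP2", "P4", "P8", "PO4", "O2")
DEAP_PERIPHERAL_8 <- c("hEOG", "vEOG", "zEMG", "tEMG", "GSR", "Resp",
                       "Plet", "Temp")

#' Adapt a DEAP-shaped per-subject array pair to a recording
#'
#' The published preprocessed per-subject structure is a pair of arrays:
#' `data` of shape trials x channels x samples (40 x 40 x 8064) and
#' `labels` of shape trials x 4 (valence, arousal, dominance, liking).
#' Channels 1-32 are EEG in the standard montage order, channels 33-40 the
#' eight peripheral sensors. Only valence and arousal are retained. The
#' gated source files themselves are never read by this package; callers
#' load the arrays however they obtained them.
#'
#' @param data 3-d numeric array, trials x 40 channels x samples.
#' @param labels Numeric matrix, trials x >= 2, columns valence then
#'   arousal (ratings on 1-9).
#' @param subject_id Character scalar.
#' @param rate_hz Sampling rate of the arrays (default 128).
#' @return An `emo_recording` with 32 EEG and 8 peripheral channels.
#' @export
deap_to_recording <- function(data, labels, subject_id, rate_hz = 128) {
  if (length(dim(data)) != 3L || dim(data)[2L] != 40L)
    stop("`data` must be a trials x 40 channels x samples array")
  n_trials <- dim(data)[1L]
  labels <- as.matrix(labels)
  if (nrow(labels) != n_trials || ncol(labels) < 2L)
    stop("`labels` must have one row per trial and >= 2 columns")
  trials <- lapply(seq_len(n_trials), function(t) {
    sig <- matrix(data[t, , ], nrow = 40L)
    eeg <- sig[1:32, , drop = FALSE]
    per <- sig[33:40, , drop = FALSE]
    rownames(eeg) <- DEAP_EEG_32
    rownames(per) <- DEAP_PERIPHERAL_8
    new_trial(sprintf("trial%02d", t), eeg, per,
              labels[t, 1L], labels[t, 2L])
  })
  new_recording(subject_id, trials, rate_hz)
}
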