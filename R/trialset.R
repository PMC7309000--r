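#' Single multi-channel EEG recording
#'
#' Lightweight container for one continuous multi-channel recording: a
#' channels x samples numeric matrix (microvolts), its sampling rate, ordered
#' 10-20 channel labels, and an optional subset of labels flagged as
#' electro-oculogram (EOG) reference channels used by
#' [remove_eog_regression()].
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector, one label per row of `data`.
#' @param eog_labels character vector, subset of `channel_labels` flagged as
#'   EOG channels (may be empty).
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(500), 2, 250), fs = 250, c("Fp1", "Fp2"))
#' @export
eeg_recording <- function(data, fs, channel_labels, eog_labels = character()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  stopifnot(is.numeric(fs), length(fs) == 1L)
  fs <- as.numeric(fs)
  if (fs <= 0) stop("`fs` must be positive")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    stop("length(channel_labels) must equal the number of data rows")
  }
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  eog_labels <- as.character(eog_labels)
  if (!all(eog_labels %in% channel_labels)) {
    stop("eog_labels must be a subset of channel_labels")
  }
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         eog_labels = eog_labels),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$fs))
  if (length(x$eog_labels)) {
    cat("  EOG channels:", paste(x$eog_labels, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Labeled set of fixed-length EEG trials
#'
#' The pipeline's unit of work: a trials x channels x samples array with a
#' common sampling rate, per-trial class labels and optional valence/arousal
#' ratings on the 1-9 self-assessment scale.
#'
#' Two label schemes are supported. Under `"binary"` labels are +1 (positive
#' emotion) and -1 (negative emotion). Under `"quadrant"` labels are 1-4 for
#' the four valence-arousal quadrants HAHV, HALV, LAHV, LALV obtained by
#' thresholding both ratings at 5 (values of exactly 5 count as High); see
#' [assign_labels()].
#'
#' @param trials numeric array, trials x channels x samples.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one per channel.
#' @param labels integer per-trial class label (see Details).
#' @param ratings optional trials x 2 matrix of (valence, arousal) ratings on
#'   a 1-9 scale.
#' @param label_scheme `"binary"` or `"quadrant"`.
#' @param eog_labels labels flagged as EOG channels.
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(trials, fs, channel_labels, labels,
                      ratings = NULL, label_scheme = c("binary", "quadrant"),
                      eog_labels = character()) {
  label_scheme <- match.arg(label_scheme)
  if (length(dim(trials)) != 3L) stop("`trials` must be a 3-d array")
  storage.mode(trials) <- "double"
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  fs <- as.numeric(fs)
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != dim(trials)[2L]) {
    stop("length(channel_labels) must equal dim(trials)[2]")
  }
  labels <- as.integer(labels)
  if (length(labels) != dim(trials)[1L]) {
    stop("length(labels) must equal the number of trials")
  }
  ok <- switch(label_scheme,
    binary = all(labels %in% c(-1L, 1L)),
    quadrant = all(labels %in% 1:4)
  )
  if (!ok) stop("labels inconsistent with label_scheme '", label_scheme, "'")
  if (!is.null(ratings)) {
    ratings <- as.matrix(ratings)
    if (nrow(ratings) != dim(trials)[1L] || ncol(ratings) < 2L) {
      stop("`ratings` must have one row per trial and >= 2 columns")
    }
  }
  eog_labels <- as.character(eog_labels)
  if (!all(eog_labels %in% channel_labels)) {
    stop("eog_labels must be a subset of channel_labels")
  }
  structure(
    list(trials = trials, fs = fs, channel_labels = channel_labels,
         labels = labels, ratings = ratings, label_scheme = label_scheme,
         eog_labels = eog_labels),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf("<trial_set> %d trials x %d channels x %d samples @ %g Hz (%s labels)\n",
              d[1], d[2], d[3], x$fs, x$label_scheme))
  print(table(label = x$labels))
  invisible(x)
}

#' @export
dim.trial_set <- function(x) dim(x$trials)

#' Number of trials in a trial set
#' @param x a [trial_set()].
#' @return integer trial count.
#' @export
n_trials <- function(x) dim(x$trials)[1L]

#' Extract one trial as an `eeg_recording`
#' @param x a [trial_set()].
#' @param i trial index.
#' @return an [eeg_recording()].
#' @export
get_trial <- function(x, i) {
  stopifnot(inherits(x, "trial_set"), i >= 1L, i <= n_trials(x))
  eeg_recording(x$trials[i, , , drop = TRUE], x$fs, x$channel_labels,
                x$eog_labels)
}

#' Electrode montage with hemispheric asymmetry pairs
#'
#' A montage is the ordered set of channel labels plus an ordered list of
#' (left, right) electrode pairs used for rational-asymmetry features. The
#' default pairs are the seven classic hemispheric mirrors
#' FP1-FP2, F7-F8, F3-F4, T7-T8, C3-C4, P7-P8, P3-P4.
#'
#' @param channel_labels character vector of channel labels.
#' @param asymmetry_pairs two-column character matrix (left, right); defaults
#'   to [default_asymmetry_pairs()]. Pair membership is checked
#'   case-insensitively against `channel_labels`.
#' @return An object of class `montage`.
#' @export
montage <- function(channel_labels, asymmetry_pairs = default_asymmetry_pairs()) {
  channel_labels <- as.character(channel_labels)
  asymmetry_pairs <- as.matrix(asymmetry_pairs)
  if (ncol(asymmetry_pairs) != 2L) stop("asymmetry_pairs needs 2 columns")
  lower <- tolower(channel_labels)
  for (r in seq_len(nrow(asymmetry_pairs))) {
    for (side in 1:2) {
      if (!tolower(asymmetry_pairs[r, side]) %in% lower) {
        stop(sprintf("asymmetry pair %s-%s: channel '%s' not in montage",
                     asymmetry_pairs[r, 1], asymmetry_pairs[r, 2],
                     asymmetry_pairs[r, side]))
      }
    }
  }
  structure(list(channel_labels = channel_labels,
                 asymmetry_pairs = asymmetry_pairs),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d channels, %d asymmetry pairs\n",
              length(x$channel_labels), nrow(x$asymmetry_pairs)))
  invisible(x)
}

#' The seven default hemispheric asymmetry pairs
#' @return a 7 x 2 character matrix of (left, right) labels.
#' @export
default_asymmetry_pairs <- function() {
  cbind(left  = c("Fp1", "F7", "F3", "T7", "C3", "P7", "P3"),
        right = c("Fp2", "F8", "F4", "T8", "C4", "P8", "P4"))
}

#' Standard channel layouts
#'
#' `"deap32"` is the 32-channel layout of the widely used DEAP affective EEG
#' corpus (128 Hz preprocessed signals). `"online30"` is a 30-EEG-channel
#' 10-20 cap as used by amplifier setups that devote 4 of 32+ electrodes to
#' EOG; with the seven default asymmetry pairs it yields a 748-column feature
#' matrix (24 x 30 + 4 x 7), while `"deap32"` yields 796.
#'
#' @param layout `"deap32"` or `"online30"`.
#' @return a [montage()].
#' @export
standard_montage <- function(layout = c("deap32", "online30")) {
  layout <- match.arg(layout)
  labs <- switch(layout,
    deap32 = c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5",
               "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz", "Fp2", "AF4",
               "Fz", "F4", "F8", "FC6", "FC2", "Cz", "C4", "T8", "CP6",
               "CP2", "P4", "P8", "PO4", "O2"),
    online30 = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FT7", "FC3",
                 "FCz", "FC4", "FT8", "T7", "C3", "Cz", "C4", "T8", "TP7",
                 "CP3", "CPz", "CP4", "TP8", "P7", "P3", "Pz", "P4", "P8",
                 "O1", "Oz", "O2")
  )
  montage(labs)
}

# case-insensitive channel index lookup; errors with the offending label
match_channel <- function(label, channel_labels) {
  i <- match(tolower(label), tolower(channel_labels))
  if (is.na(i)) stop("channel '", label, "' not found in channel labels")
  i
}
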