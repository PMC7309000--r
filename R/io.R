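# Trial-set I/O: a plain numeric interchange format (raw little-endian
# doubles + JSON sidecar) for lossless round trips, and minimal EDF
# (European Data Format) support for interoperability with EEG tooling.
# No installed R package reads EDF, so the 16-bit container is implemented
# here directly; EDF round trips are exact only up to its 16-bit
# quantization.

sidecar_path <- function(path) paste0(path, ".json")

required_sidecar <- c("fs", "channel_labels", "labels", "label_scheme")

write_sidecar <- function(ts, path, dims) {
  meta <- list(fs = ts$fs, channel_labels = ts$channel_labels,
               eog_labels = ts$eog_labels, labels = ts$labels,
               ratings = ts$ratings, label_scheme = ts$label_scheme,
               asymmetry_pairs = default_asymmetry_pairs(),
               dims = dims, byte_order = "little")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("sidecar file not found: ", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (f in required_sidecar) {
    if (is.null(meta[[f]])) stop("sidecar is missing required field '", f, "'")
  }
  meta
}

#' Write / read trial sets on disk
#'
#' Two formats. `"interchange"`: `<path>.dat` holds the trial tensor as raw
#' little-endian doubles (trial-major, then channel, then sample) and
#' `<path>.json` a sidecar with `fs`, `channel_labels`, `eog_labels`,
#' `labels`, `ratings`, `label_scheme`, `asymmetry_pairs` and `dims`;
#' round trips are numerically exact. `"edf"`: `<path>.edf` stores each trial
#' as one EDF data record (16-bit samples, per-channel physical scaling) plus
#' the same JSON sidecar for labels; round trips are exact up to the 16-bit
#' quantization step. Missing sidecar fields and channel-count mismatches
#' raise errors naming the offending field.
#'
#' @param ts a [trial_set()].
#' @param path file path without extension.
#' @param format `"interchange"` or `"edf"`.
#' @return `write_trials` returns `path` invisibly; `read_trials` a
#'   [trial_set()].
#' @export
write_trials <- function(ts, path, format = c("interchange", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(ts, "trial_set"))
  d <- dim(ts$trials)
  if (format == "interchange") {
    con <- file(paste0(path, ".dat"), "wb")
    on.exit(close(con))
    writeBin(as.vector(aperm(ts$trials, c(3, 2, 1))), con,
             size = 8, endian = "little")
  } else {
    write_edf(ts, paste0(path, ".edf"))
  }
  write_sidecar(ts, path, d)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path, format = c("interchange", "edf")) {
  format <- match.arg(format)
  meta <- read_sidecar(path)
  ratings <- if (is.null(meta$ratings) || length(meta$ratings) == 0) {
    NULL
  } else as.matrix(meta$ratings)
  if (format == "interchange") {
    d <- as.integer(meta$dims)
    if (length(meta$channel_labels) != d[2]) {
      stop("sidecar field 'channel_labels' (", length(meta$channel_labels),
           ") does not match dims channel count (", d[2], ")")
    }
    con <- file(paste0(path, ".dat"), "rb")
    on.exit(close(con))
    v <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
    trials <- aperm(array(v, dim = d[c(3, 2, 1)]), c(3, 2, 1))
  } else {
    edf <- read_edf(paste0(path, ".edf"))
    if (length(meta$channel_labels) != dim(edf)[2]) {
      stop("EDF channel count (", dim(edf)[2],
           ") does not match sidecar field 'channel_labels' (",
           length(meta$channel_labels), ")")
    }
    trials <- edf
  }
  trial_set(trials, meta$fs, meta$channel_labels, meta$labels,
            ratings = ratings, label_scheme = meta$label_scheme,
            eog_labels = unlist(meta$eog_labels))
}

edf_pad <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

edf_num <- function(x, width = 8) edf_pad(formatC(x, format = "g", digits = 6), width)

write_edf <- function(ts, file) {
  d <- dim(ts$trials)
  ns <- d[2]
  con <- file(file, "wb")
  on.exit(close(con))
  hdr <- paste0(edf_pad("0", 8), edf_pad("X", 80), edf_pad("eegselect", 80),
                edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
                edf_pad(256 * (ns + 1), 8), edf_pad("", 44),
                edf_pad(d[1], 8), edf_num(d[3] / ts$fs), edf_pad(ns, 4))
  pmin_ <- pmax_ <- numeric(ns)
  for (c_ in seq_len(ns)) {
    x <- ts$trials[, c_, ]
    r <- range(x)
    if (r[1] == r[2]) r <- r + c(-1, 1)
    # widen so the formatted (6-significant-digit) bounds still bracket data
    r <- r + c(-1, 1) * diff(r) * 1e-4
    pmin_[c_] <- as.numeric(edf_num(r[1]))
    pmax_[c_] <- as.numeric(edf_num(r[2]))
  }
  sig <- paste0(
    paste(vapply(ts$channel_labels, edf_pad, "", width = 16), collapse = ""),
    strrep(edf_pad("", 80), ns),
    strrep(edf_pad("uV", 8), ns),
    paste(vapply(pmin_, edf_num, ""), collapse = ""),
    paste(vapply(pmax_, edf_num, ""), collapse = ""),
    strrep(edf_pad(-32768, 8), ns),
    strrep(edf_pad(32767, 8), ns),
    strrep(edf_pad("", 80), ns),
    strrep(edf_pad(d[3], 8), ns),
    strrep(edf_pad("", 32), ns))
  writeBin(charToRaw(paste0(hdr, sig)), con)
  for (i in seq_len(d[1])) {
    for (c_ in seq_len(ns)) {
      x <- ts$trials[i, c_, ]
      dig <- round((x - pmin_[c_]) / (pmax_[c_] - pmin_[c_]) * 65535 - 32768)
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2, endian = "little")
    }
  }
}

read_edf <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256))
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  n_rec <- as.integer(fld(hdr, 237, 8))
  ns <- as.integer(fld(hdr, 253, 4))
  sig <- rawToChar(readBin(con, "raw", 256 * ns))
  grab <- function(offset, width) {
    vapply(seq_len(ns), function(i) {
      trimws(substr(sig, offset + (i - 1) * width + 1, offset + i * width))
    }, character(1))
  }
  pmin_ <- as.numeric(grab(16 * ns + 80 * ns + 8 * ns, 8))
  pmax_ <- as.numeric(grab(16 * ns + 80 * ns + 16 * ns, 8))
  dmin_ <- as.numeric(grab(16 * ns + 80 * ns + 24 * ns, 8))
  dmax_ <- as.numeric(grab(16 * ns + 80 * ns + 32 * ns, 8))
  nsamp <- as.integer(grab(16 * ns + 80 * ns + 40 * ns + 80 * ns, 8))
  trials <- array(0, dim = c(n_rec, ns, nsamp[1]))
  for (i in seq_len(n_rec)) {
    for (c_ in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nsamp[c_], size = 2,
                     signed = TRUE, endian = "little")
      trials[i, c_, ] <- (dig - dmin_[c_]) / (dmax_[c_] - dmin_[c_]) *
        (pmax_[c_] - pmin_[c_]) + pmin_[c_]
    }
  }
  trials
}

#' Ingest arrays in the 40-trial affective-corpus layout
#'
#' Accepts the layout used by the DEAP affective EEG corpus: a
#' trials x channels x samples data array whose first 32 channels are EEG
#' (the remainder are peripheral signals and are dropped), and a trials x 4
#' ratings array ordered (valence, arousal, dominance, liking). Quadrant
#' labels are derived from the first two rating columns with
#' [assign_labels()].
#'
#' @param data numeric array, trials x channels x samples (e.g.
#'   40 x 40 x 8064).
#' @param ratings trials x >= 2 ratings array.
#' @param fs sampling rate of the stored signals (128 Hz for the
#'   preprocessed corpus).
#' @return a [trial_set()] with 32 EEG channels, quadrant labels, and the
#'   (valence, arousal) ratings attached.
#' @export
as_trial_set_deap <- function(data, ratings, fs = 128) {
  if (length(dim(data)) != 3) stop("`data` must be trials x channels x samples")
  if (dim(data)[2] < 32) stop("expected at least 32 channels, got ", dim(data)[2])
  ratings <- as.matrix(ratings)
  if (nrow(ratings) != dim(data)[1] || ncol(ratings) < 2) {
    stop("`ratings` must have one row per trial and >= 2 columns")
  }
  va <- ratings[, 1:2, drop = FALSE]
  colnames(va) <- c("valence", "arousal")
  trial_set(data[, 1:32, , drop = FALSE], fs,
            standard_montage("deap32")$channel_labels,
            assign_labels(va, "quadrant"), ratings = va,
            label_scheme = "quadrant")
}
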