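#' Specification for the synthetic EEG generator
#'
#' Describes a set of class-separable synthetic EEG trials: a 1/f^alpha
#' Gaussian background on every channel, with class-specific multiplicative
#' power factors applied to chosen frequency bands on chosen channel subsets.
#' Effects are applied directly to the spectral coefficients (each bin in the
#' band is scaled by `sqrt(factor)`), so the planted between-class band-power
#' ratio equals `factor` exactly in expectation -- which makes the generator
#' usable as a ground-truth oracle for the downstream feature extractor and
#' selector.
#'
#' @param n_trials_per_class trials per class (>= 1).
#' @param n_channels number of EEG channels; 32 and 30 map to
#'   [standard_montage()] layouts, other counts get generic labels.
#' @param fs sampling rate in Hz.
#' @param duration trial length in seconds.
#' @param alpha 1/f spectral exponent of the background (1 = pink, typical
#'   resting EEG).
#' @param amplitude background RMS amplitude in microvolts.
#' @param band_effects list of effects, each
#'   `list(class =, band = c(low, high) | band name, channels =, factor =)`;
#'   `channels` are indices or labels; `factor` a positive power multiplier.
#'   `NULL` means [default_band_effects()] for the scheme.
#' @param label_scheme `"binary"` (+1/-1) or `"quadrant"` (classes 1-4).
#' @param seed integer RNG seed; same spec + same seed gives bitwise-identical
#'   output.
#' @return An object of class `synth_spec`.
#' @seealso [generate_synthetic_trials()]
#' @export
synth_spec <- function(n_trials_per_class = 20, n_channels = 32, fs = 128,
                       duration = 60, alpha = 1, amplitude = 10,
                       band_effects = NULL,
                       label_scheme = c("binary", "quadrant"), seed = 1) {
  label_scheme <- match.arg(label_scheme)
  if (n_trials_per_class < 1) stop("invalid spec: n_trials_per_class must be >= 1")
  if (fs <= 0) stop("invalid spec: fs must be positive")
  if (duration <= 0) stop("invalid spec: duration must be positive")
  if (n_channels < 1) stop("invalid spec: n_channels must be >= 1")
  if (is.null(band_effects)) band_effects <- default_band_effects(label_scheme)
  for (ef in band_effects) {
    if (!all(c("class", "band", "channels", "factor") %in% names(ef))) {
      stop("each band effect needs fields class, band, channels, factor")
    }
    if (ef$factor <= 0) stop("invalid spec: band-effect factors must be > 0")
  }
  structure(
    list(n_trials_per_class = n_trials_per_class, n_channels = n_channels,
         fs = fs, duration = duration, alpha = alpha, amplitude = amplitude,
         band_effects = band_effects, label_scheme = label_scheme,
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

#' Default planted class effects
#'
#' One band-power effect per class on the first eight (frontal-ish) channels,
#' factor 2: binary classes get alpha (+1) vs beta (-1) enhancement; quadrant
#' classes 1-4 get alpha, beta, theta, gamma respectively. A factor of 2 is a
#' strong but physiologically plausible band-power modulation.
#'
#' @param label_scheme `"binary"` or `"quadrant"`.
#' @return list of effect descriptors for [synth_spec()].
#' @export
default_band_effects <- function(label_scheme = c("binary", "quadrant")) {
  label_scheme <- match.arg(label_scheme)
  ch <- 1:8
  if (label_scheme == "binary") {
    list(list(class = 1L, band = "alpha", channels = ch, factor = 2),
         list(class = -1L, band = "beta", channels = ch, factor = 2))
  } else {
    list(list(class = 1L, band = "alpha", channels = ch, factor = 2),
         list(class = 2L, band = "beta", channels = ch, factor = 2),
         list(class = 3L, band = "theta", channels = ch, factor = 2),
         list(class = 4L, band = "gamma", channels = ch, factor = 2))
  }
}

synth_channel_labels <- function(n_channels) {
  if (n_channels == 32) return(standard_montage("deap32")$channel_labels)
  if (n_channels == 30) return(standard_montage("online30")$channel_labels)
  paste0("Ch", seq_len(n_channels))
}

resolve_band <- function(band) {
  if (is.character(band)) {
    b <- default_bands()[[band]]
    if (is.null(b)) stop("unknown band name '", band, "'")
    c(b$low, b$high)
  } else {
    as.numeric(band)
  }
}

#' Generate class-separable synthetic EEG trials
#'
#' Each trial/channel is synthesized in the frequency domain: complex Gaussian
#' coefficients shaped by f^(-alpha/2), scaled so the background RMS equals
#' `spec$amplitude`, then multiplied by `sqrt(factor)` on bins inside each
#' planted band effect for the matching class/channels. Labels are emitted in
#' class blocks, exactly `n_trials_per_class` each; ratings are drawn uniformly
#' in the half-interval matching the trial's class ([5, 9] on the High side,
#' [1, 5) on the Low side of the valence/arousal threshold).
#'
#' @param spec a [synth_spec()].
#' @return a [trial_set()] with `ratings` attached.
#' @examples
#' ts <- generate_synthetic_trials(synth_spec(n_trials_per_class = 2,
#'                                            n_channels = 4, duration = 2))
#' dim(ts)
#' @export
generate_synthetic_trials <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- floor(spec$fs * spec$duration)
  if (n < 4) stop("invalid spec: trial too short")
  classes <- if (spec$label_scheme == "binary") c(1L, -1L) else 1:4
  n_trials <- spec$n_trials_per_class * length(classes)
  labs <- synth_channel_labels(spec$n_channels)

  freqs <- seq_len(floor(n / 2)) * spec$fs / n   # positive-frequency bins
  base_amp <- freqs^(-spec$alpha / 2)
  # expected variance of the real signal from unit complex-normal coefficients
  nyq <- n %% 2 == 0
  amp2 <- base_amp^2
  ev <- (2 * sum(amp2) - if (nyq) amp2[length(amp2)] else 0) / n^2
  base_amp <- base_amp * spec$amplitude / sqrt(ev)

  # per class x channel amplitude shaping with planted effects folded in
  shape_for <- function(cls, ch) {
    a <- base_amp
    for (ef in spec$band_effects) {
      if (ef$class != cls) next
      idx <- if (is.character(ef$channels)) {
        vapply(ef$channels, match_channel, integer(1), channel_labels = labs)
      } else as.integer(ef$channels)
      if (!ch %in% idx) next
      band <- resolve_band(ef$band)
      sel <- freqs >= band[1] & freqs < band[2]
      a[sel] <- a[sel] * sqrt(ef$factor)
    }
    a
  }

  trials <- array(0, dim = c(n_trials, spec$n_channels, n))
  labels <- rep(classes, each = spec$n_trials_per_class)
  nf <- length(freqs)

  with_seed(spec$seed, {
    for (i in seq_len(n_trials)) {
      for (ch in seq_len(spec$n_channels)) {
        a <- shape_for(labels[i], ch)
        z <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) /
          sqrt(2)
        if (nyq) z[nf] <- complex(real = stats::rnorm(1), imaginary = 0)
        s <- a * z
        # Hermitian spectrum -> real signal
        full <- if (nyq) c(0, s, Conj(rev(s[-nf]))) else c(0, s, Conj(rev(s)))
        trials[i, ch, ] <- Re(stats::fft(full, inverse = TRUE)) / n
      }
    }
    ratings <- synth_ratings(labels, spec$label_scheme)
    trial_set(trials, spec$fs, labs, labels, ratings = ratings,
              label_scheme = spec$label_scheme)
  })
}

# ratings consistent with the class: High side uniform [5, 9],
# Low side uniform [1, 5)
synth_ratings <- function(labels, label_scheme) {
  hi <- function(k) stats::runif(k, 5, 9)
  lo <- function(k) stats::runif(k, 1, 5 - 1e-9)
  m <- matrix(NA_real_, length(labels), 2,
              dimnames = list(NULL, c("valence", "arousal")))
  for (i in seq_along(labels)) {
    if (label_scheme == "binary") {
      m[i, 1] <- if (labels[i] == 1L) hi(1) else lo(1)
      m[i, 2] <- stats::runif(1, 1, 9)
    } else {
      # 1 = HAHV, 2 = HALV, 3 = LAHV, 4 = LALV
      m[i, 1] <- if (labels[i] %in% c(1L, 3L)) hi(1) else lo(1)
      m[i, 2] <- if (labels[i] %in% c(1L, 2L)) hi(1) else lo(1)
    }
  }
  m
}

# evaluate `expr` under a local RNG seeded with `seed`, restoring global state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Add a synthetic ocular artifact to frontal channels
#'
#' Generates one low-frequency (< 4 Hz) blink-like source per trial, adds it
#' to every frontal channel (labels starting Fp/AF/F) with per-channel mixing
#' coefficients, and appends the source itself as an explicit `"VEOG"` channel
#' flagged in `eog_labels`. The clean input and the mixing coefficients are
#' returned so that artifact-removal stages can be validated against ground
#' truth.
#'
#' @param ts a [trial_set()].
#' @param eog_amplitude RMS amplitude of the EOG source in microvolts (>= 0;
#'   0 leaves the EEG channels untouched).
#' @param seed RNG seed for the source and the mixing coefficients.
#' @return list with elements `trials` (contaminated [trial_set()] with the
#'   EOG channel appended), `clean` (the input), and `mixing` (named vector of
#'   per-frontal-channel regression coefficients onto the EOG channel).
#' @export
inject_eog <- function(ts, eog_amplitude = 80, seed = 1) {
  stopifnot(inherits(ts, "trial_set"))
  if (eog_amplitude < 0) stop("eog_amplitude must be >= 0")
  d <- dim(ts$trials)
  frontal <- grep("^(Fp|AF|F[0-9z])", ts$channel_labels, ignore.case = TRUE)
  with_seed(seed, {
    mixing <- stats::setNames(stats::runif(length(frontal), 0.3, 1),
                              ts$channel_labels[frontal])
    new <- array(0, dim = c(d[1], d[2] + 1L, d[3]))
    new[, seq_len(d[2]), ] <- ts$trials
    if (d[3] >= 24) {
      bf <- signal::butter(2, min(4 / (ts$fs / 2), 0.99), type = "low")
    }
    for (i in seq_len(d[1])) {
      src <- stats::rnorm(d[3])
      if (d[3] >= 24) src <- signal::filtfilt(bf, src)
      s <- stats::sd(src)
      src <- if (s > 0) src / s * eog_amplitude else src
      new[i, d[2] + 1L, ] <- src
      for (j in seq_along(frontal)) {
        new[i, frontal[j], ] <- new[i, frontal[j], ] + mixing[j] * src
      }
    }
    out <- trial_set(new, ts$fs, c(ts$channel_labels, "VEOG"), ts$labels,
                     ratings = ts$ratings, label_scheme = ts$label_scheme,
                     eog_labels = "VEOG")
    list(trials = out, clean = ts, mixing = mixing)
  })
}
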