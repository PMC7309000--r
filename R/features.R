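#' Default EEG frequency bands
#'
#' theta 4-8, alpha 8-14, beta 14-30, gamma 30-50 Hz. Band intervals are
#' half-open `[low, high)` so the four bands partition 4-50 Hz.
#'
#' @return named list of `list(low, high)` band specs.
#' @export
default_bands <- function() {
  list(theta = list(low = 4, high = 8),
       alpha = list(low = 8, high = 14),
       beta  = list(low = 14, high = 30),
       gamma = list(low = 30, high = 50))
}

#' Time-domain statistical features of one channel
#'
#' The classic six-statistic vector: mean, population standard deviation
#' (1/N), mean absolute first and second differences, and their
#' sigma-normalized versions. Normalized differences are defined as 0 when
#' the standard deviation is 0 (constant signal).
#'
#' @param x numeric signal of length >= 3.
#' @return named numeric vector
#'   `c(mean, sd, mad1, nmad1, mad2, nmad2)`.
#' @examples
#' statistical_features(c(1, 2, 3, 4))
#' @export
statistical_features <- function(x) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples (second difference undefined)")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  d1 <- mean(abs(diff(x)))
  d2 <- mean(abs(x[-(1:2)] - x[seq_len(n - 2)]))
  norm <- function(d) if (sigma > 0) d / sigma else 0
  c(mean = mu, sd = sigma, mad1 = d1, nmad1 = norm(d1),
    mad2 = d2, nmad2 = norm(d2))
}

#' Welch power spectral density estimate
#'
#' Hann-windowed averaged periodogram with 50% segment overlap, one-sided
#' density scaling: `sum(psd) * df` approximates the signal's mean square
#' power.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length (default `min(256, length(x))`).
#' @param overlap fractional overlap between segments.
#' @return list with `freq` (Hz) and `psd` (power / Hz).
#' @export
welch_psd <- function(x, fs, nperseg = min(256L, length(x)), overlap = 0.5) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(nperseg) / nperseg))  # periodic Hann
  u <- sum(win^2)
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- Mod(stats::fft(seg)[seq_len(nf)])^2
    acc <- acc + sp
  }
  psd <- acc / (length(starts) * u * fs)
  scale <- rep(2, nf); scale[1] <- 1
  if (nperseg %% 2L == 0L) scale[nf] <- 1
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = psd * scale)
}

#' Band power from the Welch spectrum
#'
#' Integrates the one-sided Welch PSD over each half-open band
#' `[low, high)`.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param bands named list of band specs as in [default_bands()].
#' @param nperseg Welch segment length.
#' @return named numeric vector of band powers (same units as `x^2`).
#' @export
band_power <- function(x, fs, bands = default_bands(), nperseg = 256L) {
  for (b in bands) {
    if (b$high > fs / 2) stop("band above the Nyquist frequency")
  }
  w <- welch_psd(x, fs, nperseg = min(nperseg, length(x)))
  df <- w$freq[2] - w$freq[1]
  vapply(bands, function(b) {
    sum(w$psd[w$freq >= b$low & w$freq < b$high]) * df
  }, numeric(1))
}

# zero-phase Butterworth band-pass used for band-limited variance
band_filter <- function(x, fs, low, high, order = 4) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Band-limited differential entropy
#'
#' For each band the signal is zero-phase band-pass filtered, the band
#' variance estimated with the 1/N convention, and the Gaussian closed form
#' `h = 0.5 * log(2 * pi * e * sigma^2)` applied (natural logarithm). A
#' zero-variance band yields `-Inf` as a sentinel.
#'
#' Doubling the signal amplitude increases every band's entropy by exactly
#' `log(2)`; `h = 0` at band variance `1 / (2 * pi * e)`.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param bands named list of band specs.
#' @return named numeric vector of differential entropies (nats).
#' @export
differential_entropy <- function(x, fs, bands = default_bands()) {
  for (b in bands) {
    if (b$high > fs / 2) stop("band above the Nyquist frequency")
  }
  vapply(bands, function(b) {
    y <- band_filter(x, fs, b$low, b$high)
    v <- mean((y - mean(y))^2)
    if (v == 0) -Inf else 0.5 * log(2 * pi * exp(1) * v)
  }, numeric(1))
}

#' Rational asymmetry features of one trial
#'
#' For each hemispheric (left, right) electrode pair and each band, the ratio
#' of the band differential entropies `h(left) / h(right)`. A zero
#' denominator yields `NaN` as a flagged sentinel.
#'
#' @param trial channels x samples numeric matrix (one trial).
#' @param mont a [montage()] whose labels match the trial rows.
#' @param fs sampling rate in Hz.
#' @param bands named list of band specs.
#' @return named numeric vector, pair-major then band
#'   (`Fp1-Fp2:theta`, ...); `4 * P` values for P pairs.
#' @export
rasm_features <- function(trial, mont, fs, bands = default_bands()) {
  pairs <- mont$asymmetry_pairs
  de <- matrix(NA_real_, nrow(trial), length(bands))
  need <- unique(vapply(c(pairs[, 1], pairs[, 2]), match_channel, integer(1),
                        channel_labels = mont$channel_labels))
  for (i in need) de[i, ] <- differential_entropy(trial[i, ], fs, bands)
  out <- numeric(0)
  for (r in seq_len(nrow(pairs))) {
    li <- match_channel(pairs[r, 1], mont$channel_labels)
    ri <- match_channel(pairs[r, 2], mont$channel_labels)
    ratio <- ifelse(de[ri, ] == 0, NaN, de[li, ] / de[ri, ])
    names(ratio) <- paste0(pairs[r, 1], "-", pairs[r, 2], ":", names(bands))
    out <- c(out, ratio)
  }
  out
}

#' Wavelet entropy and energy features of one channel
#'
#' Five-level db4 decomposition ([dwt_periodized()]); per detail level the
#' energy `ENG_j = sum(D_j^2)` and the (unnormalized, log-energy style)
#' entropy `ENT_j = -sum(D_j^2 * log(D_j^2))` with the `0 * log 0 = 0`
#' convention. Level band edges are derived from the actual sampling rate
#' (level j spans `fs / 2^(j+1)` to `fs / 2^j` Hz) and carried in the names.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz (used only for the band labels).
#' @param wavelet wavelet name, see [dwt_periodized()].
#' @param levels decomposition depth.
#' @return named numeric vector, `ENT` for levels 1..levels then `ENG`.
#' @export
wavelet_features <- function(x, fs, wavelet = "db4", levels = 5) {
  dec <- dwt_periodized(x, wavelet, levels)
  lab <- vapply(seq_len(levels), function(j) {
    sprintf("D%d.%g-%gHz", j, fs / 2^(j + 1), fs / 2^j)
  }, character(1))
  ent <- vapply(dec$details, function(d) {
    c2 <- d^2
    -sum(ifelse(c2 > 0, c2 * log(c2), 0))
  }, numeric(1))
  eng <- vapply(dec$details, function(d) sum(d^2), numeric(1))
  stats::setNames(c(ent, eng), c(paste0("ent.", lab), paste0("eng.", lab)))
}

#' Extract the full multi-domain feature matrix
#'
#' Assembles, for every trial, the complete feature bank: 6 time-domain
#' statistics, 4 Welch band powers and 4 band differential entropies per EEG
#' channel, 4 rational-asymmetry ratios per electrode pair, and 10 wavelet
#' entropy/energy values per channel. With C channels and P pairs the matrix
#' has `F = 24 C + 4 P` columns: 796 for the 32-channel layout and 748 for
#' the 30-channel layout with the seven default pairs.
#'
#' Column order is family-major, then channel (or pair) in montage order,
#' then feature/band: `stat`, `bp`, `de`, `rasm`, `dwt`. Names follow
#' `family:channel:feature` (e.g. `de:Fp1:alpha`), and the index ranges of
#' the five families are attached as attribute `"family_slices"`, so
#' selected-feature masks are portable across runs.
#'
#' @param ts a [trial_set()] (EOG channels, if any, are excluded).
#' @param mont a [montage()]; default derives from the set's channel labels
#'   with the seven standard asymmetry pairs.
#' @param bands named list of band specs.
#' @param wavelet,levels wavelet decomposition settings.
#' @param nperseg Welch segment length.
#' @return trials x F numeric matrix with column names and attribute
#'   `family_slices`.
#' @export
extract_features <- function(ts, mont = NULL, bands = default_bands(),
                             wavelet = "db4", levels = 5, nperseg = 256L) {
  stopifnot(inherits(ts, "trial_set"))
  eeg <- setdiff(ts$channel_labels, ts$eog_labels)
  if (is.null(mont)) {
    # keep the standard asymmetry pairs whose members are present
    pairs <- default_asymmetry_pairs()
    have <- apply(pairs, 1, function(p) all(tolower(p) %in% tolower(eeg)))
    mont <- montage(eeg, pairs[have, , drop = FALSE])
  }
  miss <- setdiff(tolower(mont$channel_labels), tolower(eeg))
  if (length(miss)) {
    stop("montage channels not present in the trial set: ",
         paste(miss, collapse = ", "))
  }
  chans <- mont$channel_labels
  C <- length(chans)
  P <- nrow(mont$asymmetry_pairs)
  nb <- length(bands)
  stat_names <- c("mean", "sd", "mad1", "nmad1", "mad2", "nmad2")
  cols <- c(
    paste0("stat:", rep(chans, each = 6), ":", rep(stat_names, C)),
    paste0("bp:", rep(chans, each = nb), ":", rep(names(bands), C)),
    paste0("de:", rep(chans, each = nb), ":", rep(names(bands), C))
  )
  ch_idx <- vapply(chans, match_channel, integer(1),
                   channel_labels = ts$channel_labels)
  first <- ts$trials[1, ch_idx[1], ]
  dwt_names <- names(wavelet_features(first, ts$fs, wavelet, levels))
  rasm_names <- if (P == 0) character(0) else {
    paste0("rasm:",
           rep(paste0(mont$asymmetry_pairs[, 1], "-",
                      mont$asymmetry_pairs[, 2]), each = nb),
           ":", rep(names(bands), P))
  }
  cols <- c(cols, rasm_names,
            paste0("dwt:", rep(chans, each = 2 * levels), ":",
                   rep(dwt_names, C)))
  n <- n_trials(ts)
  out <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  slices <- list(stat = seq_len(6 * C),
                 bp = 6 * C + seq_len(nb * C),
                 de = (6 + nb) * C + seq_len(nb * C),
                 rasm = (6 + 2 * nb) * C + seq_len(nb * P),
                 dwt = (6 + 2 * nb) * C + nb * P + seq_len(2 * levels * C))
  for (i in seq_len(n)) {
    tr <- ts$trials[i, ch_idx, , drop = TRUE]
    if (is.null(dim(tr))) tr <- matrix(tr, nrow = 1)
    de_mat <- t(vapply(seq_len(C), function(c) {
      differential_entropy(tr[c, ], ts$fs, bands)
    }, numeric(nb)))
    stat <- as.vector(vapply(seq_len(C), function(c) {
      statistical_features(tr[c, ])
    }, numeric(6)))
    bp <- as.vector(vapply(seq_len(C), function(c) {
      band_power(tr[c, ], ts$fs, bands, nperseg)
    }, numeric(nb)))
    rasm <- numeric(0)
    for (r in seq_len(P)) {
      li <- match_channel(mont$asymmetry_pairs[r, 1], chans)
      ri <- match_channel(mont$asymmetry_pairs[r, 2], chans)
      rasm <- c(rasm, ifelse(de_mat[ri, ] == 0, NaN,
                             de_mat[li, ] / de_mat[ri, ]))
    }
    dwt <- as.vector(vapply(seq_len(C), function(c) {
      wavelet_features(tr[c, ], ts$fs, wavelet, levels)
    }, numeric(2 * levels)))
    out[i, ] <- c(stat, bp, as.vector(t(de_mat)), rasm, dwt)
  }
  attr(out, "family_slices") <- slices
  out
}
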