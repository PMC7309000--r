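# Periodized orthonormal discrete wavelet transform.
#
# No wavelet package ships with this stack, so the Mallat pyramid with
# periodic (circular) boundary handling is implemented directly; with an
# orthonormal filter pair the transform conserves energy exactly, which the
# test suite checks against sum(x^2).

# Daubechies scaling (low-pass) filters, sum = sqrt(2)
daubechies_filters <- list(
  db2 = c(0.48296291314469025, 0.83651630373746899,
          0.22414386804185735, -0.12940952255092145),
  db4 = c(0.23037781330885523, 0.71484657055254153, 0.63088076792959036,
          -0.02798376941698385, -0.18703481171888114, 0.03084138183598697,
          0.03288301166698295, -0.01059740178499728)
)

#' Periodized discrete wavelet transform
#'
#' Multi-level analysis with circular boundary handling; for orthonormal
#' Daubechies filters the coefficient energy equals the signal energy. Odd
#' lengths at any level are extended by wrapping one sample.
#'
#' @param x numeric signal.
#' @param wavelet `"db4"` (default) or `"db2"`.
#' @param levels decomposition depth; `length(x)` must be at least
#'   `2^levels`.
#' @return list with `details` (list `D1`..`D<levels>`, finest first) and
#'   `approx` (final approximation coefficients).
#' @export
dwt_periodized <- function(x, wavelet = "db4", levels = 5) {
  lo <- daubechies_filters[[wavelet]]
  if (is.null(lo)) stop("unsupported wavelet '", wavelet, "'")
  if (length(x) < 2^levels) {
    stop("signal too short for ", levels, "-level decomposition")
  }
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)   # quadrature mirror filter
  details <- vector("list", levels)
  a <- as.numeric(x)
  for (j in seq_len(levels)) {
    if (length(a) %% 2L == 1L) a <- c(a, a[1])
    n <- length(a)
    half <- n %/% 2L
    appr <- numeric(half)
    det <- numeric(half)
    pos <- 2L * (seq_len(half) - 1L) - (L %/% 2L - 1L)
    for (tap in seq_len(L)) {
      seg <- a[((pos + tap - 1L) %% n) + 1L]
      appr <- appr + lo[tap] * seg
      det <- det + hi[tap] * seg
    }
    details[[j]] <- det
    a <- appr
  }
  names(details) <- paste0("D", seq_len(levels))
  list(details = details, approx = a)
}
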