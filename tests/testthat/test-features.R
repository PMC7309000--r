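test_that("statistical features match hand evaluation", {
  f <- statistical_features(c(1, 2, 3, 4))
  expect_equal(unname(f), c(2.5, sqrt(1.25), 1, 1 / sqrt(1.25), 2, 2 / sqrt(1.25)))
  # constant signal: degenerate variance maps normalized diffs to 0
  fc <- statistical_features(rep(7, 10))
  expect_equal(unname(fc), c(7, 0, 0, 0, 0, 0))
  # shift invariance of everything but the mean
  x <- rnorm(50)
  f1 <- statistical_features(x); f2 <- statistical_features(x + 10)
  expect_equal(f2["mean"] - f1["mean"], c(mean = 10))
  expect_equal(f1[-1], f2[-1])
  expect_error(statistical_features(c(1, 2)), "3 samples")
})

test_that("band power localizes tones and satisfies Parseval", {
  fs <- 128
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  bp <- band_power(x, fs)
  expect_gt(bp["alpha"] / sum(bp), 0.9)
  # white-noise total power across a partition of [0, fs/2)
  set.seed(2)
  w <- rnorm(fs * 8, sd = 2)
  full <- band_power(w, fs, bands = list(all = list(low = 0, high = fs / 2)))
  expect_equal(unname(full), 4, tolerance = 0.1 * 4)
  expect_equal(unname(band_power(rep(0, 512), fs)), rep(0, 4))
  expect_error(band_power(x, fs, bands = list(b = list(low = 10, high = 100))),
               "Nyquist")
})

test_that("differential entropy matches the entropy integral and scaling law", {
  fs <- 128
  set.seed(3)
  x <- rnorm(fs * 8)
  # numerical integration oracle: -integral p log p for N(0, sigma)
  num_entropy <- function(sigma) {
    stats::integrate(function(u) {
      p <- stats::dnorm(u, sd = sigma)
      ifelse(p > 0, -p * log(p), 0)
    }, -10 * sigma, 10 * sigma)$value
  }
  de <- differential_entropy(x, fs)
  # recover the band variance from the entropy and check the closed form
  for (b in names(de)) {
    sigma <- sqrt(exp(2 * de[[b]]) / (2 * pi * exp(1)))
    expect_equal(de[[b]], num_entropy(sigma), tolerance = 1e-3)
  }
  # scaled to unit band variance the entropy is that of N(0,1)
  y <- band_filter(x, fs, 8, 14)
  xu <- x / sqrt(mean((y - mean(y))^2))
  expect_equal(unname(differential_entropy(xu, fs)["alpha"]),
               num_entropy(1), tolerance = 1e-3)
  expect_equal(num_entropy(1), 0.5 * log(2 * pi * exp(1)), tolerance = 1e-9)
  # amplitude scaling by k shifts every band by exactly log(k)
  for (k in c(2, 5)) {
    expect_equal(differential_entropy(k * x, fs) - de,
                 setNames(rep(log(k), 4), names(de)), tolerance = 1e-10)
  }
  # band variance 1/(2 pi e) is the zero of the entropy
  xz <- xu / sqrt(2 * pi * exp(1))
  expect_equal(unname(differential_entropy(xz, fs)["alpha"]), 0,
               tolerance = 1e-12)
})

test_that("rational asymmetry is 1 for mirrored data and reciprocal on swap", {
  fs <- 128
  set.seed(4)
  left <- rnorm(fs * 2)
  trial <- rbind(left, left)
  m <- tiny_montage()
  r <- rasm_features(trial, m, fs)
  expect_length(r, 4)
  expect_equal(unname(r), rep(1, 4))

  right <- rnorm(fs * 2) * 3
  r1 <- rasm_features(rbind(left, right), m, fs)
  r2 <- rasm_features(rbind(right, left), m, fs)
  expect_equal(unname(r1 * r2), rep(1, 4), tolerance = 1e-10)
  expect_error(montage(c("C3", "Cz"), cbind("C3", "C4")), "C4")
})

test_that("wavelet features match the independent multiresolution oracle", {
  # frozen reference values computed with an independent db4 implementation
  # (periodized 5-level decomposition of sin(2 pi 7 t) + 0.5 sin(2 pi 20 t),
  # fs = 128, N = 256)
  fs <- 128
  t <- (0:255) / fs
  x <- sin(2 * pi * 7 * t) + 0.5 * sin(2 * pi * 20 * t)
  w <- wavelet_features(x, fs)
  ref_eng <- c(D1 = 1.530108023963, D2 = 26.841107713666, D3 = 41.682363615311,
               D4 = 89.909260547168, D5 = 0.031208533890)
  ref_ent <- c(D1 = 6.302376965376, D2 = 15.088947851209,
               D3 = -27.597455772206, D4 = -186.050150471957,
               D5 = 0.172964768000)
  expect_equal(unname(w[6:10]), unname(ref_eng), tolerance = 1e-8)
  expect_equal(unname(w[1:5]), unname(ref_ent), tolerance = 1e-8)
  # level band labels derive from fs: D1 spans fs/4 .. fs/2
  expect_match(names(w)[1], "D1.32-64Hz", fixed = TRUE)

  expect_equal(unname(wavelet_features(rep(0, 64), fs)), rep(0, 10))
  # unit impulse: total coefficient energy is 1 (orthonormal transform)
  dec <- dwt_periodized(c(1, rep(0, 63)), "db4", 5)
  expect_equal(sum(sapply(dec$details, function(d) sum(d^2))) +
                 sum(dec$approx^2), 1, tolerance = 1e-10)
  expect_error(dwt_periodized(rnorm(16), "db4", 5), "too short")
})

test_that("wavelet transform conserves energy on random signals", {
  set.seed(6)
  for (i in 1:100) {
    n <- 32 * sample(2:20, 1)
    x <- rnorm(n) * runif(1, 0.1, 10)
    dec <- dwt_periodized(x, "db4", 5)
    tot <- sum(sapply(dec$details, function(d) sum(d^2))) + sum(dec$approx^2)
    expect_lt(abs(tot - sum(x^2)) / sum(x^2), 1e-6)
  }
})

test_that("full extraction obeys the 24C + 4P column formula", {
  ts <- make_noise_trials(8, n_per_class = 1, n_channels = 32, duration = 2)
  m <- extract_features(ts)
  expect_equal(ncol(m), 24 * 32 + 4 * 7)  # 796
  sl <- attr(m, "family_slices")
  expect_equal(lengths(sl)[["stat"]], 6 * 32)
  expect_equal(lengths(sl)[["rasm"]], 28)
  expect_false(anyDuplicated(colnames(m)) > 0)
  expect_false(anyNA(m))

  ts14 <- make_noise_trials(8, n_per_class = 1, n_channels = 14, duration = 1)
  m14 <- extract_features(ts14, montage(ts14$channel_labels,
                                        cbind(left = c("Ch1", "Ch3", "Ch5"),
                                              right = c("Ch2", "Ch4", "Ch6"))))
  expect_equal(ncol(m14), 24 * 14 + 4 * 3)
})

test_that("extraction is per-trial independent under permutation", {
  ts <- make_noise_trials(9, n_per_class = 3, n_channels = 3, duration = 1)
  m <- extract_features(ts)
  perm <- c(4, 2, 6, 1, 3, 5)
  ts2 <- trial_set(ts$trials[perm, , ], ts$fs, ts$channel_labels,
                   ts$labels[perm], label_scheme = ts$label_scheme)
  m2 <- extract_features(ts2)
  expect_equal(m2, m[perm, ], ignore_attr = TRUE)
})

test_that("scaling a trial shifts DE features by log k and keeps RASM signs", {
  ts <- make_noise_trials(10, n_per_class = 1, n_channels = 4, duration = 1)
  m1 <- extract_features(ts)
  ts2 <- ts; ts2$trials <- ts$trials * 3
  m2 <- extract_features(ts2)
  sl <- attr(m1, "family_slices")
  expect_equal(as.vector(m2[, sl$de] - m1[, sl$de]),
               rep(log(3), 2 * length(sl$de)), tolerance = 1e-8)
  expect_equal(sign(m2[, sl$rasm]), sign(m1[, sl$rasm]))
})
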