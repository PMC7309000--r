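# Shared fixtures, all generated in code.

# two-class feature design with `n_informative` planted mean-shift columns
# (standardized shift `d`) among `n_features` standard-normal columns
make_planted_design <- function(seed, n = 60, n_features = 100,
                                n_informative = 5, d = 1.0) {
  set.seed(seed)
  x <- matrix(rnorm(n * n_features), n)
  y <- rep(c(1L, -1L), each = n / 2)
  x[y == 1L, seq_len(n_informative)] <- x[y == 1L, seq_len(n_informative)] + d
  list(x = x, y = y, informative = seq_len(n_informative))
}

# perfectly separable two-class features: informative columns put the classes
# far apart, the rest are noise
make_separable_design <- function(seed, n = 40, n_features = 10) {
  set.seed(seed)
  x <- matrix(rnorm(n * n_features, sd = 0.1), n)
  y <- rep(c(1L, -1L), each = n / 2)
  x[, 1] <- x[, 1] + ifelse(y == 1L, 5, -5)
  x[, 2] <- x[, 2] + ifelse(y == 1L, -5, 5)
  list(x = x, y = y)
}

# minimal trial set with given dimensions and iid normal samples
make_noise_trials <- function(seed, n_per_class = 3, n_channels = 4,
                              fs = 128, duration = 1) {
  generate_synthetic_trials(synth_spec(
    n_trials_per_class = n_per_class, n_channels = n_channels, fs = fs,
    duration = duration, band_effects = list(), seed = seed))
}

# tiny montage over generic labels for rasm tests
tiny_montage <- function(labels = c("C3", "C4")) {
  montage(labels, cbind(left = "C3", right = "C4"))
}
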