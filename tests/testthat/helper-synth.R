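# Shared fixtures, built in code at test time.

# Small cohort spec for fast unit tests (full epoch geometry, fewer subjects).
mini_spec <- function(seed = 1, n_trials = 10, ...) {
  cohort_spec(n_patients = 3, n_controls = 3, n_trials = n_trials, seed = seed,
              ...)
}

# A quick noise trial set: n trials of white noise at the default geometry.
noise_trialset <- function(n_trials = 6, n_samples = 1024, fs = 1024,
                           seed = 42, ...) {
  tvpac:::with_seed(seed, {
    trial_set(matrix(stats::rnorm(n_trials * n_samples), n_trials),
              fs = fs, onset_index = 103L, ...)
  })
}

# Gaussian feature matrix with n_signal separated features, the rest noise.
gauss_fm <- function(n_a = 10, n_b = 8, p = 50, n_signal = 1, delta = 3,
                     seed = 1) {
  tvpac:::with_seed(seed, {
    X <- matrix(stats::rnorm((n_a + n_b) * p), n_a + n_b)
    if (n_signal > 0) {
      X[seq_len(n_a), seq_len(n_signal)] <-
        X[seq_len(n_a), seq_len(n_signal)] + delta
    }
    feature_matrix(X, rep(c("patient", "control"), c(n_a, n_b)))
  })
}

theta <- band_spec("theta", 4, 8)
beta1 <- band_spec("beta1", 13, 20)

# Circular standard deviation of a phase sample.
circ_sd <- function(x) sqrt(-2 * log(max(1e-12, Mod(mean(exp(1i * x))))))
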