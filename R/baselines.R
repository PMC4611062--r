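#' Time-locked-averaging feature vector
#'
#' The classical representation of an event-related response: the across-trial
#' ensemble average of the recording, band-passed into each of the 7 rhythm
#' bands plus a wide band (1-45 Hz), concatenated band-major. A 1024-sample
#' epoch yields (7 + 1) x 1024 = 8192 features.
#'
#' @param ts A [trial_set()].
#' @param bands List of [band_spec()] (default [default_bands()]).
#' @param wideband Two-element numeric, edges of the appended wide band in Hz
#'   (default `c(1, 45)`).
#' @return Named numeric feature vector.
#' @export
tla_features <- function(ts, bands = default_bands(), wideband = c(1, 45)) {
  stopifnot(inherits(ts, "trial_set"))
  all_bands <- c(bands, list(band_spec("wide", wideband[1L], wideband[2L])))
  out <- lapply(all_bands, function(b) colMeans(filter_trialset(ts, b)$data))
  v <- unlist(out, use.names = FALSE)
  names(v) <- unlist(lapply(all_bands, function(b) {
    sprintf("tla:%s@t%04d", b$name, seq_len(ncol(ts$data)))
  }))
  v
}

#' Averaged-spectrogram (STFT) feature vector
#'
#' Magnitude spectrogram of each trial via the short-time Fourier transform,
#' averaged across trials and flattened frequency-major. Defaults: 128-sample
#' Hann window, 50% overlap, one-sided spectrum kept up to `f_max` Hz.
#'
#' @param ts A [trial_set()].
#' @param window_n STFT window length in samples (default 128).
#' @param overlap Overlap in samples (default `window_n / 2`).
#' @param f_max Highest retained frequency in Hz (default 45).
#' @return Named numeric feature vector of length
#'   `n_retained_bins x n_time_slices`.
#' @export
stft_features <- function(ts, window_n = 128, overlap = window_n / 2,
                          f_max = 45) {
  stopifnot(inherits(ts, "trial_set"))
  if (window_n > ncol(ts$data)) stop("STFT window longer than the epoch")
  acc <- NULL
  for (tr in seq_len(nrow(ts$data))) {
    sg <- signal::specgram(ts$data[tr, ], n = window_n, Fs = ts$fs,
                           window = window_n, overlap = overlap)
    mag <- Mod(sg$S)
    if (is.null(acc)) {
      acc <- mag
      freqs <- sg$f
      times <- sg$t
    } else {
      acc <- acc + mag
    }
  }
  acc <- acc / nrow(ts$data)
  keep <- freqs <= f_max
  acc <- acc[keep, , drop = FALSE]
  v <- as.vector(t(acc))   # frequency-major: all time slices of f1, then f2...
  names(v) <- as.vector(t(outer(freqs[keep], seq_along(times),
                                function(f, k) sprintf("stft:%gHz@w%02d", f, k))))
  v
}

# Morlet continuous wavelet transform magnitudes of the columns of X
# (samples x series) at the given frequencies. omega0 is the
# centre-frequency / bandwidth ratio of the analytic Morlet mother wavelet.
morlet_cwt_mag <- function(X, fs, freqs, omega0 = 6) {
  n <- nrow(X)
  Xf <- stats::mvfft(X)
  w <- 2 * pi * fs * c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / n
  out <- array(0, dim = c(length(freqs), n, ncol(X)))
  for (k in seq_along(freqs)) {
    s <- omega0 / (2 * pi * freqs[k])
    psi <- pi^(-0.25) * sqrt(2 * pi * s * fs / n) * exp(-((s * w - omega0)^2) / 2)
    psi[w < 0] <- 0
    Zk <- stats::mvfft(Xf * psi, inverse = TRUE)
    out[k, , ] <- Mod(Zk)
  }
  out
}

#' Averaged Morlet-scalogram feature vector
#'
#' Magnitude scalogram of each trial under an analytic Morlet wavelet
#' (centre-frequency/bandwidth ratio `omega0 = 6`), averaged across trials,
#' time-decimated, and flattened frequency-major. Defaults: 45 linear
#' frequencies 1-45 Hz, every 16th sample kept on the time axis.
#'
#' @param ts A [trial_set()].
#' @param freqs Analysis frequencies in Hz (default `1:45`).
#' @param omega0 Morlet centre-frequency/bandwidth ratio (default 6).
#' @param time_step Time-axis decimation step in samples (default 16).
#' @return Named numeric feature vector of length
#'   `length(freqs) x ceiling(n_samples / time_step)`.
#' @export
wavelet_features <- function(ts, freqs = 1:45, omega0 = 6, time_step = 16) {
  stopifnot(inherits(ts, "trial_set"))
  if (any(freqs <= 0) || any(freqs >= ts$fs / 2)) {
    stop("wavelet frequencies must lie in (0, fs/2)")
  }
  mag <- morlet_cwt_mag(t(ts$data), ts$fs, freqs, omega0)
  avg <- apply(mag, c(1L, 2L), mean)               # freq x samples
  keep <- seq(1L, ncol(avg), by = time_step)
  avg <- avg[, keep, drop = FALSE]
  v <- as.vector(t(avg))
  names(v) <- as.vector(t(outer(freqs, keep,
                                function(f, k) sprintf("wt:%gHz@t%04d", f, k))))
  v
}

#' Build a cohort-level feature matrix under a chosen representation
#'
#' Applies one of the four representations -- time-resolved PAC, time-locked
#' averaging, averaged spectrogram, or averaged Morlet scalogram -- to every
#' subject's trial set, producing the [feature_matrix()] consumed by the
#' ranking and classification stages. All four flow through those stages
#' unchanged, which is what makes their head-to-head comparison fair.
#'
#' @param ts_list List of [trial_set()] objects with group labels.
#' @param kind `"pac"`, `"tla"`, `"stft"` or `"wt"`.
#' @param bands Rhythm catalogue for `"pac"`/`"tla"`.
#' @param step_ms PAC stepping-window length (ms).
#' @param ... Further arguments for the representation function
#'   ([stft_features()], [wavelet_features()], [tla_features()]).
#' @return A [feature_matrix()].
#' @export
representation_matrix <- function(ts_list, kind = c("pac", "tla", "stft", "wt"),
                                  bands = default_bands(), step_ms = 20, ...) {
  kind <- match.arg(kind)
  stopifnot(length(ts_list) >= 2L)
  if (kind == "pac") {
    return(pac_feature_matrix(lapply(ts_list, pac_tensor, bands = bands,
                                     step_ms = step_ms)))
  }
  fun <- switch(kind,
                tla = function(ts) tla_features(ts, bands = bands, ...),
                stft = function(ts) stft_features(ts, ...),
                wt = function(ts) wavelet_features(ts, ...))
  rows <- lapply(ts_list, fun)
  feats <- do.call(rbind, rows)
  rownames(feats) <- vapply(ts_list, `[[`, "", "subject_id")
  ids <- data.frame(feature = names(rows[[1L]]), stringsAsFactors = FALSE)
  feature_matrix(feats, vapply(ts_list, `[[`, "", "group"), ids)
}
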