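#' Define a frequency band
#'
#' @param name Short label, e.g. `"theta"`.
#' @param f_low,f_high Band edges in Hz, `0 < f_low < f_high`.
#' @return A `band_spec` object (named list).
#' @export
band_spec <- function(name, f_low, f_high) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(f_low) || !is.finite(f_high) || f_low <= 0 || f_high <= f_low) {
    stop("invalid band: need 0 < f_low < f_high")
  }
  structure(list(name = name, f_low = f_low, f_high = f_high),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band %s: %g-%g Hz>\n", x$name, x$f_low, x$f_high))
  invisible(x)
}

#' The seven canonical brain-rhythm bands
#'
#' Returns the catalogue of EEG rhythms used throughout the pipeline:
#' delta 2-4, theta 4-8, alpha1 8-10, alpha2 10-13, beta1 13-20,
#' beta2 20-30 and gamma 30-45 Hz -- a contiguous, non-overlapping
#' partition of 2-45 Hz, sorted by lower edge.
#'
#' @return A list of 7 [band_spec()] objects.
#' @examples
#' vapply(default_bands(), `[[`, "", "name")
#' @export
default_bands <- function() {
  list(
    band_spec("delta",  2, 4),
    band_spec("theta",  4, 8),
    band_spec("alpha1", 8, 10),
    band_spec("alpha2", 10, 13),
    band_spec("beta1",  13, 20),
    band_spec("beta2",  20, 30),
    band_spec("gamma",  30, 45)
  )
}

# Cache of designed Butterworth band-pass filters keyed by (f_low, f_high, fs).
.filter_cache <- new.env(parent = emptyenv())

# 3rd-order Butterworth band-pass for a band at sampling rate fs, factored
# into second-order sections for numerical stability: the transfer function
# from signal::butter is split at its poles (conjugate pairs -> biquads), and
# the band-pass zeros (three each at z = +/-1) give every biquad the
# numerator (1, 0, -1). The overall gain is applied once.
butter_band <- function(band, fs) {
  if (!inherits(band, "band_spec")) stop("band must be a band_spec")
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  if (band$f_high >= fs / 2) {
    stop(sprintf("band %s (%g-%g Hz) reaches the Nyquist frequency at fs = %g",
                 band$name, band$f_low, band$f_high, fs))
  }
  key <- sprintf("%.9g_%.9g_%.9g", band$f_low, band$f_high, fs)
  hit <- .filter_cache[[key]]
  if (!is.null(hit)) return(hit)
  flt <- signal::butter(3, c(band$f_low, band$f_high) / (fs / 2), type = "pass")
  poles <- polyroot(rev(flt$a / flt$a[1L]))
  tol <- 1e-6
  cplx <- poles[Im(poles) > tol]
  real_p <- sort(Re(poles[abs(Im(poles)) <= tol]))
  if (2L * length(cplx) + length(real_p) != length(flt$a) - 1L ||
      length(real_p) %% 2L != 0L) {
    stop("unexpected pole configuration while factoring the band-pass filter")
  }
  dens <- lapply(cplx, function(p) c(1, -2 * Re(p), Mod(p)^2))
  for (k in seq_len(length(real_p) / 2)) {
    r <- real_p[(2L * k - 1L):(2L * k)]
    dens <- c(dens, list(c(1, -sum(r), prod(r))))
  }
  sos <- list(gain = flt$b[1L] / flt$a[1L], dens = dens,
              b = flt$b, a = flt$a)
  .filter_cache[[key]] <- sos
  sos
}

# Single-pass IIR filtering (zero initial conditions) of the columns of X,
# split into the moving-average and autoregressive parts of the difference
# equation; both run in C via stats::filter.
iir_cols <- function(b, a, X) {
  nb <- length(b)
  n <- nrow(X)
  if (a[1L] != 1) {
    b <- b / a[1L]
    a <- a / a[1L]
  }
  v <- stats::filter(rbind(matrix(0, nb - 1L, ncol(X)), X), b,
                     method = "convolution", sides = 1L)
  v <- v[(nb - 1L) + seq_len(n), , drop = FALSE]
  y <- stats::filter(v, -a[-1L], method = "recursive")
  matrix(as.numeric(y), n)
}

# Single pass of a second-order-section cascade over the columns of X.
sos_cols <- function(sos, X) {
  for (den in sos$dens) X <- iir_cols(c(1, 0, -1), den, X)
  sos$gain * X
}

# Forward-backward (zero-phase) filtering of each column of X through the
# biquad cascade, with odd-symmetric edge padding of length
# 3 * (filter order). The effective magnitude response is the squared
# single-pass response; the phase response is zero.
zp_filter_mat <- function(flt, X) {
  npad <- 3L * (max(length(flt$b), length(flt$a)) - 1L)
  n <- nrow(X)
  if (n <= npad) {
    stop(sprintf("signal too short for zero-phase filtering (need > %d samples)",
                 npad))
  }
  top <- 2 * X[rep(1L, npad), , drop = FALSE] - X[(npad + 1L):2L, , drop = FALSE]
  bot <- 2 * X[rep(n, npad), , drop = FALSE] -
    X[(n - 1L):(n - npad), , drop = FALSE]
  Xp <- rbind(top, X, bot)
  Y <- sos_cols(flt, Xp)
  Y <- sos_cols(flt, Y[nrow(Y):1L, , drop = FALSE])
  Y[(nrow(Y) - npad) : (npad + 1L), , drop = FALSE]
}

zp_filter <- function(flt, x) {
  as.numeric(zp_filter_mat(flt, matrix(x, ncol = 1L)))
}

#' Zero-phase band-pass filtering
#'
#' Applies a 3rd-order Butterworth band-pass filter in zero-phase mode
#' (forward-backward filtering with odd-symmetric edge padding), so the output
#' has no group delay and the effective magnitude response is the squared
#' single-pass response.
#'
#' @param x Real numeric series.
#' @param band A [band_spec()].
#' @param fs Sampling rate in Hz; the band must lie below `fs / 2`.
#' @return Filtered series, same length as `x`.
#' @examples
#' fs <- 1024
#' y <- bandpass(sin(2 * pi * 6 * (0:2047) / fs), band_spec("theta", 4, 8), fs)
#' @export
bandpass <- function(x, band, fs) {
  if (!all(is.finite(x))) stop("bandpass() requires finite input")
  zp_filter(butter_band(band, fs), x)
}

#' Band-pass filter a trial set on the concatenated recording
#'
#' Trials are concatenated in stored order into one long series, band-pass
#' filtered in zero-phase mode, and re-segmented to the original trial layout.
#' Filtering the concatenation (rather than each 1 s trial) gives the IIR
#' filter a long warm-up and matches how multi-trial recordings are filtered
#' before epoch-wise analysis; seam discontinuities between consecutive trials
#' are accepted.
#'
#' @param ts A [trial_set()].
#' @param band A [band_spec()].
#' @return A `trial_set` with the same shape and metadata, filtered data.
#' @export
filter_trialset <- function(ts, band) {
  stopifnot(inherits(ts, "trial_set"))
  long <- as.vector(t(ts$data))            # trial-major concatenation
  filt <- zp_filter(butter_band(band, ts$fs), long)
  out <- ts
  out$data <- matrix(filt, nrow = nrow(ts$data), byrow = TRUE,
                     dimnames = dimnames(ts$data))
  out
}
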