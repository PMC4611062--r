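#' Construct a single-sensor multi-trial epoch set
#'
#' The basic data container: one subject's epoched recording for one stimulus
#' condition, as a trials x samples matrix with sampling metadata. Epochs are
#' assumed stimulus-locked, with `onset_index` marking the sample of stimulus
#' onset (1-based), e.g. a -100..+900 ms epoch at 1024 Hz has
#' `onset_index = 103`.
#'
#' @param data Numeric matrix, rows = trials, columns = samples; all finite.
#' @param fs Sampling rate in Hz.
#' @param subject_id Subject identifier string.
#' @param group One of `"patient"`, `"control"`, `"unknown"`.
#' @param condition One of `"target"`, `"nontarget"`.
#' @param onset_index 1-based sample index of stimulus onset.
#' @return A `trial_set` object.
#' @export
trial_set <- function(data, fs, subject_id = "s1", group = "unknown",
                      condition = "target",
                      onset_index = 1L) {
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 1L || ncol(data) < 2L) {
    stop("trial_set data must be a numeric matrix with >= 1 trial, >= 2 samples")
  }
  if (!all(is.finite(data))) stop("trial_set data must be finite")
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  group <- match.arg(group, c("patient", "control", "unknown"))
  condition <- match.arg(condition, c("target", "nontarget"))
  onset_index <- as.integer(onset_index)
  if (onset_index < 1L || onset_index > ncol(data)) {
    stop("onset_index must lie within the epoch")
  }
  structure(
    list(subject_id = as.character(subject_id), group = group,
         condition = condition, fs = fs, onset_index = onset_index,
         data = data),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf(
    "<trial_set %s [%s/%s]: %d trials x %d samples @ %g Hz, onset at sample %d>\n",
    x$subject_id, x$group, x$condition, nrow(x$data), ncol(x$data), x$fs,
    x$onset_index))
  invisible(x)
}

#' @export
dim.trial_set <- function(x) dim(x$data)

# Latency of each sample relative to stimulus onset, in ms.
trial_latency_ms <- function(ts) {
  (seq_len(ncol(ts$data)) - ts$onset_index) / ts$fs * 1000
}

#' Drop artifact-contaminated trials by amplitude threshold
#'
#' Removes trials whose absolute peak exceeds `amp_thresh`, emulating an
#' on-line amplitude-based artifact rejector.
#'
#' @param ts A [trial_set()].
#' @param amp_thresh Positive rejection threshold (same units as the data).
#' @return The trial set with offending trials removed; the number of dropped
#'   trials is reported via `message()` and stored in attribute `"n_rejected"`.
#' @export
reject_trials <- function(ts, amp_thresh) {
  stopifnot(inherits(ts, "trial_set"))
  if (!is.numeric(amp_thresh) || length(amp_thresh) != 1L || amp_thresh <= 0) {
    stop("amp_thresh must be a positive scalar")
  }
  peak <- apply(abs(ts$data), 1L, max)
  keep <- peak <= amp_thresh
  if (!any(keep)) {
    stop(sprintf("reject_trials: all %d trials exceed threshold %g",
                 nrow(ts$data), amp_thresh))
  }
  n_rej <- sum(!keep)
  if (n_rej > 0L) {
    message(sprintf("reject_trials: dropped %d of %d trials (|peak| > %g)",
                    n_rej, nrow(ts$data), amp_thresh))
  }
  out <- ts
  out$data <- ts$data[keep, , drop = FALSE]
  attr(out, "n_rejected") <- n_rej
  out
}

#' Grand-average waveform across subjects
#'
#' Averages trials within each subject and then subjects, giving the
#' grand-averaged event-related response used to locate deflection windows.
#'
#' @param ts_list A list of [trial_set()] objects with equal epoch geometry.
#' @return A list with `waveform` (numeric vector), `latency_ms` (per sample,
#'   relative to onset) and `n_subjects`.
#' @export
ga_waveform <- function(ts_list) {
  if (inherits(ts_list, "trial_set")) ts_list <- list(ts_list)
  stopifnot(length(ts_list) >= 1L, all(vapply(ts_list, inherits, TRUE, "trial_set")))
  ns <- vapply(ts_list, function(t) ncol(t$data), 0L)
  if (length(unique(ns)) != 1L) stop("trial sets differ in epoch length")
  avg <- rowMeans(vapply(ts_list, function(t) colMeans(t$data),
                         numeric(ns[1L])))
  list(waveform = avg, latency_ms = trial_latency_ms(ts_list[[1L]]),
       n_subjects = length(ts_list))
}

#' Report local extrema of a grand-average waveform
#'
#' Helper for choosing deflection windows by eye: lists local minima and
#' maxima of the (optionally smoothed) grand average, with latencies.
#'
#' @param ga Output of [ga_waveform()].
#' @param smooth_ms Width of a moving-average smoother applied before peak
#'   picking (ms); 0 disables smoothing.
#' @return A data frame with columns `latency_ms`, `value`, `kind`
#'   (`"min"`/`"max"`), sorted by latency.
#' @export
ga_extrema <- function(ga, smooth_ms = 20) {
  w <- ga$waveform
  if (smooth_ms > 0) {
    fs <- 1000 / diff(ga$latency_ms[1:2])
    k <- max(1L, round(smooth_ms / 1000 * fs))
    w <- stats::filter(w, rep(1 / k, k), sides = 2)
    w[is.na(w)] <- ga$waveform[is.na(w)]
    w <- as.numeric(w)
  }
  d <- diff(w)
  s <- sign(d)
  turn <- which(s[-1] != 0 & s[-length(s)] != 0 & s[-1] != s[-length(s)]) + 1L
  if (length(turn) == 0L) {
    return(data.frame(latency_ms = numeric(), value = numeric(),
                      kind = character()))
  }
  data.frame(
    latency_ms = ga$latency_ms[turn],
    value = w[turn],
    kind = ifelse(s[turn] < 0, "max", "min"),
    stringsAsFactors = FALSE
  )
}
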