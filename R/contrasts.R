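#' Define a deflection latency window
#'
#' A latency interval, relative to stimulus onset, associated with one
#' morphological component of the event-related response. Windows are
#' configuration, not detection: use [ga_extrema()] to inspect the
#' grand-average waveform when choosing bounds.
#'
#' @param name One of `"N100"`, `"N200"`, `"P300"`, `"SW"`, `"custom"`.
#' @param start_ms,end_ms Window bounds in ms post-onset, `start_ms < end_ms`.
#' @return A `deflection_window` object.
#' @export
deflection_window <- function(name, start_ms, end_ms) {
  name <- match.arg(name, c("N100", "N200", "P300", "SW", "custom"))
  if (!is.finite(start_ms) || !is.finite(end_ms) || start_ms >= end_ms) {
    stop("need start_ms < end_ms")
  }
  structure(list(name = name, start_ms = start_ms, end_ms = end_ms),
            class = "deflection_window")
}

#' Default deflection windows
#'
#' Working defaults for the four canonical deflections of an auditory oddball
#' response: N100 80-140, N200 180-280, P300 280-450, SW 500-900 ms
#' post-onset. These are generic textbook latencies intended as starting
#' points; real analyses should confirm them on the grand average.
#'
#' @return Named list of [deflection_window()] objects.
#' @export
default_deflections <- function() {
  list(
    N100 = deflection_window("N100", 80, 140),
    N200 = deflection_window("N200", 180, 280),
    P300 = deflection_window("P300", 280, 450),
    SW   = deflection_window("SW", 500, 900)
  )
}

#' Element-wise mean of PAC tensors
#'
#' Grand-averages a set of per-subject coupling tensors on a
#' segment-by-segment basis. All tensors must share bands and grid.
#'
#' @param tensors List of [pac_tensor()] objects.
#' @return A `pac_tensor` with averaged values; `subject_id` is set to
#'   `"group_average(n)"`.
#' @export
group_average <- function(tensors) {
  if (inherits(tensors, "pac_tensor")) tensors <- list(tensors)
  stopifnot(length(tensors) >= 1L,
            all(vapply(tensors, inherits, TRUE, "pac_tensor")))
  ref <- tensors[[1L]]
  for (t in tensors[-1L]) {
    if (!identical(dim(t$values), dim(ref$values)) ||
        !isTRUE(all.equal(t$grid$centers_ms, ref$grid$centers_ms))) {
      stop("group_average: tensors have mismatched bands or grids")
    }
  }
  out <- ref
  out$values <- Reduce(`+`, lapply(tensors, `[[`, "values")) / length(tensors)
  out$subject_id <- sprintf("group_average(%d)", length(tensors))
  out
}

# Segment indices whose centre latency (ms post-onset) falls in the window.
window_segments <- function(tensor, w) {
  stopifnot(inherits(tensor, "pac_tensor"), inherits(w, "deflection_window"))
  centers_post <- tensor$grid$centers_ms -
    (tensor$onset_index - 0.5) / tensor$fs * 1000
  which(centers_post >= w$start_ms & centers_post <= w$end_ms)
}

#' Integrate a PAC tensor over a deflection window
#'
#' Sums the coupling values of the segments whose centres fall inside the
#' window, yielding one `[n_bands x n_bands]` connectivity snapshot.
#'
#' @param tensor A [pac_tensor()].
#' @param w A [deflection_window()].
#' @return Matrix `[n_bands x n_bands]` (upper triangle populated).
#' @export
segment_integrate <- function(tensor, w) {
  segs <- window_segments(tensor, w)
  if (length(segs) == 0L) {
    stop(sprintf("window %s (%g-%g ms) covers no segment centre",
                 w$name, w$start_ms, w$end_ms))
  }
  apply(tensor$values[, , segs, drop = FALSE], c(1L, 2L), sum)
}

contrast_core <- function(num_t, den_t, w, kind) {
  a <- segment_integrate(num_t, w)
  b <- segment_integrate(den_t, w)
  vals <- matrix(0, nrow(a), ncol(a), dimnames = dimnames(a))
  ut <- upper.tri(vals)
  vals[ut] <- (a[ut] - b[ut]) / b[ut]
  undef <- ut & b == 0
  vals[undef] <- NA_real_
  n_undef <- sum(undef)
  if (n_undef > 0L) {
    message(sprintf("%s: %d pair(s) undefined (zero denominator), flagged NA",
                    kind, n_undef))
  }
  structure(
    list(kind = kind, window = w, values = vals, n_undefined = n_undef),
    class = "contrast_pattern"
  )
}

#' Relative increase of coupling: target vs non-target responses
#'
#' For each LF -> HF pair, the window-integrated coupling of the target-
#' condition grand average minus that of the non-target grand average,
#' divided by the non-target value -- the fractional gain in coupling
#' attributable to the cognitive component of the response (+1 means +100%).
#'
#' @param target_ga,nontarget_ga Grand-averaged [pac_tensor()] objects (see
#'   [group_average()]) sharing bands and grid.
#' @param w A [deflection_window()].
#' @return A `contrast_pattern`: `[n_bands x n_bands]` signed matrix (upper
#'   triangle; zero-denominator entries flagged `NA`).
#' @export
relative_increase <- function(target_ga, nontarget_ga, w) {
  contrast_core(target_ga, nontarget_ga, w, "relative_increase")
}

#' Relative difference of coupling: patients vs controls
#'
#' As [relative_increase()], with (patient - control) / control: positive
#' entries mean stronger coupling in the patient group.
#'
#' @param patient_ga,control_ga Grand-averaged [pac_tensor()] objects.
#' @param w A [deflection_window()].
#' @return A `contrast_pattern`.
#' @export
relative_difference <- function(patient_ga, control_ga, w) {
  contrast_core(patient_ga, control_ga, w, "relative_difference")
}

#' @export
print.contrast_pattern <- function(x, ...) {
  ut <- upper.tri(x$values)
  rng <- range(x$values[ut], na.rm = TRUE)
  cat(sprintf("<contrast_pattern %s @ %s (%g-%g ms): range %.3f..%.3f, %d undefined>\n",
              x$kind, x$window$name, x$window$start_ms, x$window$end_ms,
              rng[1L], rng[2L], x$n_undefined))
  invisible(x)
}

#' Edge-list export of a contrast pattern
#'
#' @param pattern A `contrast_pattern`.
#' @return Data frame with columns `lf`, `hf`, `value`, `defined` -- one row
#'   per LF -> HF pair, suitable for graph tools.
#' @export
contrast_edges <- function(pattern) {
  stopifnot(inherits(pattern, "contrast_pattern"))
  v <- pattern$values
  idx <- which(upper.tri(v), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(
    lf = rownames(v)[idx[, 1L]],
    hf = colnames(v)[idx[, 2L]],
    value = v[idx],
    defined = is.finite(v[idx]),
    stringsAsFactors = FALSE
  )
}
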