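#' Non-overlapping stepping-window segment grid
#'
#' Tiles an epoch of `n_samples` samples into contiguous, non-overlapping
#' segments of approximately `step_ms` milliseconds. The segment count is
#' `round(n_samples / (fs * step_ms / 1000))` and boundaries are spread as
#' evenly as integer arithmetic allows, so a 1024-sample epoch at 1024 Hz with
#' 20 ms windows yields exactly 50 segments of 20-21 samples.
#'
#' @param n_samples Epoch length in samples.
#' @param fs Sampling rate in Hz.
#' @param step_ms Nominal window length in ms (default 20).
#' @return A `segment_grid`: list with `step_ms`, `n_segments`, `start`/`end`
#'   (1-based inclusive sample indices per segment), `seg_id` (per-sample
#'   segment membership) and `centers_ms` (segment centres in ms from epoch
#'   start).
#' @export
segment_grid <- function(n_samples, fs, step_ms = 20) {
  stopifnot(n_samples >= 2L, fs > 0, step_ms > 0)
  n_seg <- max(1L, round(n_samples / (fs * step_ms / 1000)))
  b <- round((0:n_seg) * n_samples / n_seg)
  start <- b[-(n_seg + 1L)] + 1L
  end <- b[-1L]
  seg_id <- rep.int(seq_len(n_seg), end - start + 1L)
  structure(
    list(step_ms = step_ms, n_segments = n_seg,
         start = as.integer(start), end = as.integer(end),
         seg_id = seg_id,
         centers_ms = (start + end - 1) / 2 / fs * 1000),
    class = "segment_grid"
  )
}

#' @export
print.segment_grid <- function(x, ...) {
  cat(sprintf("<segment_grid: %d segments of ~%g ms>\n", x$n_segments,
              x$step_ms))
  invisible(x)
}

#' Phase-locking value of a phase-difference sample
#'
#' The modulus of the mean unit phasor, `|mean(exp(1i * dphi))|`: 1 for
#' perfectly aligned phase differences, near 0 for uniformly scattered ones.
#'
#' @param deltas Numeric vector of phase differences in radians (any wrapping).
#' @return A scalar in `[0, 1]`.
#' @examples
#' plv(rep(1.234, 10))       # 1
#' plv(c(0, pi))             # 0
#' plv(c(0, pi / 2))         # sqrt(2)/2
#' @export
plv <- function(deltas) {
  if (length(deltas) < 1L || !all(is.finite(deltas))) {
    stop("plv() needs a non-empty finite phase-difference sample")
  }
  min(1, Mod(mean(exp(1i * deltas))))
}

#' Phase-difference series of the two-stage PAC estimator
#'
#' Implements the per-trial estimation chain for phase-amplitude coupling
#' between a low-frequency (LF) and a high-frequency (HF) rhythm:
#' band-pass the wide-band trial into LF and HF components; take the Hilbert
#' envelope of the HF component; band-pass that envelope (mean-subtracted)
#' within the LF range; Hilbert-transform again to obtain the phase of the
#' LF-rate amplitude modulation; and return the wrapped difference between the
#' LF phase and that modulation phase. A constant series indicates that the HF
#' envelope is locked to the LF phase (strong PAC). The chain is division-free,
#' so it is defined even when the trial carries no HF energy.
#'
#' @param trial Wide-band real series (one epoch).
#' @param lf,hf [band_spec()] objects with `lf$f_low < hf$f_low`.
#' @param fs Sampling rate in Hz.
#' @return Phase differences in (-pi, pi], same length as `trial`.
#' @export
phase_diff_series <- function(trial, lf, hf, fs) {
  check_pair(lf, hf)
  x_lf <- bandpass(trial, lf, fs)
  x_hf <- bandpass(trial, hf, fs)
  phi_lf <- Arg(hilbert_mat(matrix(x_lf, ncol = 1L))[, 1L])
  a_hf <- Mod(hilbert_mat(matrix(x_hf, ncol = 1L))[, 1L])
  env <- bandpass(a_hf - mean(a_hf), lf, fs)
  phi_mod <- Arg(hilbert_mat(matrix(env, ncol = 1L))[, 1L])
  wrap_phase(phi_lf - phi_mod)
}

check_pair <- function(lf, hf) {
  if (!inherits(lf, "band_spec") || !inherits(hf, "band_spec")) {
    stop("lf and hf must be band_spec objects")
  }
  if (lf$f_low >= hf$f_low) {
    stop(sprintf("pair order error: LF band %s must lie below HF band %s",
                 lf$name, hf$name))
  }
  invisible(TRUE)
}

#' Across-trial time-varying PLV at full temporal resolution
#'
#' At each latency, the modulus of the across-trial mean unit phasor of the
#' phase differences: `PLV(t) = |mean_j exp(1i * dphi_j(t))|`.
#'
#' @param deltas Matrix of phase differences, rows = trials, columns = samples.
#' @return Numeric vector of length `ncol(deltas)`, values in `[0, 1]`.
#' @export
tv_plv <- function(deltas) {
  deltas <- as.matrix(deltas)
  if (!all(is.finite(deltas))) stop("tv_plv() requires finite phase differences")
  if (nrow(deltas) < 2L) {
    warning("tv_plv() with a single trial is degenerate (PLV = 1 everywhere)")
  }
  pmin(1, Mod(colMeans(exp(1i * deltas))))
}

#' Windowed across-trial PLV on a stepping-window grid
#'
#' Pools the phase differences of all trials and all samples inside each
#' segment and takes the modulus of their mean unit phasor, trading temporal
#' resolution for estimator stability when few trials are available.
#'
#' @param deltas Matrix of phase differences, rows = trials, columns = samples.
#' @param grid A [segment_grid()] tiling `ncol(deltas)` samples.
#' @return Numeric vector of length `grid$n_segments`, values in `[0, 1]`.
#' @export
tv_plv_windowed <- function(deltas, grid) {
  deltas <- as.matrix(deltas)
  stopifnot(inherits(grid, "segment_grid"))
  if (length(grid$seg_id) != ncol(deltas)) {
    stop("segment grid does not tile the epoch length")
  }
  if (!all(is.finite(deltas))) {
    stop("tv_plv_windowed() requires finite phase differences")
  }
  z <- exp(1i * deltas)
  cs <- colSums(z)                       # across trials, per sample
  n_per <- nrow(deltas) * (grid$end - grid$start + 1L)
  sums <- rowsum(cbind(Re(cs), Im(cs)), grid$seg_id, reorder = TRUE)
  pmin(1, sqrt(sums[, 1L]^2 + sums[, 2L]^2) / n_per)
}

#' Canonical ordered LF-to-HF band pairs
#'
#' @param bands List of [band_spec()], sorted by `f_low`.
#' @return Data frame with columns `i`, `j` (band indices, `i < j`), `lf`,
#'   `hf` (names), in lexicographic `(i, j)` order -- the stable feature order
#'   used everywhere downstream.
#' @export
band_pairs <- function(bands = default_bands()) {
  nb <- length(bands)
  idx <- which(upper.tri(matrix(0, nb, nb)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(
    i = idx[, 1L], j = idx[, 2L],
    lf = vapply(bands, `[[`, "", "name")[idx[, 1L]],
    hf = vapply(bands, `[[`, "", "name")[idx[, 2L]],
    stringsAsFactors = FALSE
  )
}

# Shared machinery: per-band analytic decomposition of a trial set, then the
# phase-difference matrix (trials x samples) for one LF -> HF pair. First-stage
# band filtering is always done on the concatenated recording (see
# filter_trialset). With hilbert = "concat" (default) the analytic signal and
# the envelope band-pass run on the concatenation too, so Hilbert edge
# artifacts arise only at the ends of the whole recording rather than in the
# first and last ~100 ms of every trial; "trial" treats each epoch
# independently (matching phase_diff_series on a single epoch).
pac_phase_diffs <- function(ts, bands, hilbert = c("concat", "trial")) {
  hilbert <- match.arg(hilbert)
  nb <- length(bands)
  n_tr <- nrow(ts$data)
  n_s <- ncol(ts$data)
  phase <- vector("list", nb)
  amp <- vector("list", nb)
  shape <- function(long) matrix(long, nrow = n_s)   # samples x trials
  for (b in seq_len(nb)) {
    filt <- filter_trialset(ts, bands[[b]])
    if (hilbert == "concat") {
      z <- hilbert_mat(matrix(as.vector(t(filt$data)), ncol = 1L))[, 1L]
      phase[[b]] <- shape(Arg(z))
      amp[[b]] <- shape(Mod(z))
    } else {
      Z <- hilbert_mat(t(filt$data))
      phase[[b]] <- Arg(Z)
      amp[[b]] <- Mod(Z)
    }
  }
  flt_cache <- lapply(bands, butter_band, fs = ts$fs)
  function(i, j) {
    env <- amp[[j]]
    if (hilbert == "concat") {
      long <- as.vector(env)
      long <- zp_filter(flt_cache[[i]], long - mean(long))
      phi_mod <- shape(Arg(hilbert_mat(matrix(long, ncol = 1L))[, 1L]))
    } else {
      env <- sweep(env, 2L, colMeans(env))
      env <- zp_filter_mat(flt_cache[[i]], env)
      phi_mod <- Arg(hilbert_mat(env))
    }
    t(wrap_phase(phase[[i]] - phi_mod))  # trials x samples
  }
}

#' Per-subject time-resolved PAC tensor
#'
#' Runs the two-stage PAC chain for every ordered LF -> HF band pair and the
#' windowed across-trial PLV on a stepping-window grid, assembling the
#' `[n_bands x n_bands x n_segments]` coupling tensor. Only the upper triangle
#' (LF row, HF column) is populated; the diagonal and HF -> LF slots are zero.
#' With the 7 default rhythms and a 1 s epoch at 1024 Hz in 20 ms windows the
#' tensor is `[7 x 7 x 50]` with 21 populated pair slots.
#'
#' @param ts A [trial_set()] with at least 2 trials.
#' @param bands List of [band_spec()] (default [default_bands()]).
#' @param step_ms Stepping-window length in ms (default 20).
#' @param hilbert `"concat"` (default) takes the analytic signal of the
#'   concatenated filtered recording, confining Hilbert edge artifacts to the
#'   recording ends; `"trial"` transforms each epoch independently.
#' @return A `pac_tensor`: list with `values` (3-D array), `bands`, `grid`,
#'   `subject_id`, `group`, `condition`, `onset_index`, `fs`.
#' @export
pac_tensor <- function(ts, bands = default_bands(), step_ms = 20,
                       hilbert = c("concat", "trial")) {
  stopifnot(inherits(ts, "trial_set"))
  if (nrow(ts$data) < 2L) stop("pac_tensor() needs >= 2 trials")
  grid <- segment_grid(ncol(ts$data), ts$fs, step_ms)
  pairs <- band_pairs(bands)
  nb <- length(bands)
  vals <- array(0, dim = c(nb, nb, grid$n_segments))
  pd <- pac_phase_diffs(ts, bands, hilbert = match.arg(hilbert))
  for (k in seq_len(nrow(pairs))) {
    deltas <- pd(pairs$i[k], pairs$j[k])
    vals[pairs$i[k], pairs$j[k], ] <- tv_plv_windowed(deltas, grid)
  }
  band_names <- vapply(bands, `[[`, "", "name")
  dimnames(vals) <- list(band_names, band_names, NULL)
  structure(
    list(values = vals, bands = bands, grid = grid,
         subject_id = ts$subject_id, group = ts$group,
         condition = ts$condition, onset_index = ts$onset_index, fs = ts$fs),
    class = "pac_tensor"
  )
}

#' @export
print.pac_tensor <- function(x, ...) {
  cat(sprintf("<pac_tensor %s [%s/%s]: %d x %d x %d>\n", x$subject_id,
              x$group, x$condition, dim(x$values)[1L], dim(x$values)[2L],
              dim(x$values)[3L]))
  invisible(x)
}

#' Pair-by-segment matrix view of a PAC tensor
#'
#' @param tensor A [pac_tensor()].
#' @return Matrix `[n_pairs x n_segments]` in canonical [band_pairs()] order,
#'   with rownames `"lf->hf"`.
#' @export
pac_matrix <- function(tensor) {
  stopifnot(inherits(tensor, "pac_tensor"))
  pairs <- band_pairs(tensor$bands)
  m <- t(vapply(seq_len(nrow(pairs)),
                function(k) tensor$values[pairs$i[k], pairs$j[k], ],
                numeric(dim(tensor$values)[3L])))
  rownames(m) <- paste0(pairs$lf, "->", pairs$hf)
  m
}

#' Full-resolution across-trial PAC traces
#'
#' The across-trial PLV at every sample (no windowing) for every LF -> HF
#' pair -- the high-resolution counterpart of [pac_tensor()].
#'
#' @inheritParams pac_tensor
#' @return Matrix `[n_pairs x n_samples]` in canonical pair order.
#' @export
pac_fullres <- function(ts, bands = default_bands(),
                        hilbert = c("concat", "trial")) {
  stopifnot(inherits(ts, "trial_set"))
  pairs <- band_pairs(bands)
  pd <- pac_phase_diffs(ts, bands, hilbert = match.arg(hilbert))
  m <- t(vapply(seq_len(nrow(pairs)),
                function(k) tv_plv(pd(pairs$i[k], pairs$j[k])),
                numeric(ncol(ts$data))))
  rownames(m) <- paste0(pairs$lf, "->", pairs$hf)
  m
}

#' Mean and maximum coupling profiles across band pairs
#'
#' Summarises a pair-by-latency coupling matrix (or a [pac_tensor()]) by the
#' mean and the maximum over the populated LF -> HF pairs at each latency.
#'
#' @param x A `pac_tensor` or a `[n_pairs x n_latencies]` matrix such as from
#'   [pac_matrix()] or [pac_fullres()].
#' @return List with numeric vectors `mean` and `max` (per latency/segment).
#' @export
summarize_profiles <- function(x) {
  m <- if (inherits(x, "pac_tensor")) pac_matrix(x) else as.matrix(x)
  list(mean = colMeans(m), max = apply(m, 2L, max))
}
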