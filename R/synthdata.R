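#' Specify one injected phase-amplitude coupling
#'
#' Describes a high-frequency packet whose band-limited envelope follows the
#' phase of a low-frequency carrier -- the generative model the PAC estimator
#' assumes: inside a smoothly tapered latency window, the HF-band content has
#' envelope locked to `phi_LF(t) - phase_lag` with modulation depth `depth`.
#'
#' Because the estimator extracts the envelope *after* band-pass filtering,
#' the modulated content must itself be band-limited. Two constructions are
#' used, chosen automatically:
#' \describe{
#'   \item{`ssb`}{(when `f_hf + f_lf <= f_high(hf)`) a single-sideband pair of
#'     tones at `f_hf` and `f_hf + f_lf`, i.e.
#'     `Re[(1 + m e^{i(phi_LF - psi)}) e^{i phi_HF}]`, whose envelope is
#'     `|1 + m e^{i(phi_LF - psi)}| ~ 1 + m cos(phi_LF - psi)`.}
#'   \item{`beat`}{(otherwise, when `f_hf + f_lf / 2 <= f_high(hf)`) tones
#'     `f_lf / 2` apart; the rectification harmonic of the resulting deep beat
#'     puts an envelope component exactly at `f_lf`, phase-locked to
#'     `phi_LF - phase_lag`. Needed when the LF frequency exceeds the HF
#'     band's width (e.g. beta2 -> gamma), where no band-limited signal can
#'     carry first-order envelope modulation at `f_lf`; the effective
#'     modulation is weaker and grows nonlinearly (but monotonically) with
#'     `depth`.}
#' }
#'
#' Depth semantics: within every trial the envelope is modulated with a fixed
#' ratio (`mod_ratio`), and `depth` controls the *across-trial consistency* of
#' the envelope's phase lag behind the LF carrier: at depth `m` the per-trial
#' lag is `phase_lag + e_j` with `e_j` uniform on `+/- pi * (1 - m)`. Depth 1
#' locks the lag in every trial; depth 0 randomises it completely, which is
#' exactly the null of the across-trial phase-locking estimator. Because the
#' modulation amplitude never changes, groups differing only in depth have
#' *identical* amplitude, spectral and envelope-shape statistics -- the
#' contrast is purely one of phase coupling, invisible to amplitude-based
#' representations. The packet is additionally RMS-normalised and its latency
#' jittered by `+/- jitter_ms` per trial (induced bursts are not sample-locked
#' to the stimulus; the injected coupling travels with the packet and its own
#' LF carrier, while spurious evoked locking between the fixed ERP and a fixed
#' burst transient is destroyed).
#'
#' @param lf,hf Band names from [default_bands()] (e.g. `"theta"`, `"beta1"`).
#' @param f_lf,f_hf Carrier frequencies in Hz, inside their bands; the implied
#'   sideband must also fit inside the HF band (see above).
#' @param window_ms Two-element numeric, coupling window in ms post-onset.
#' @param depth_patient,depth_control Coupling depth m in `[0, 1]` per group
#'   (across-trial phase-consistency, see above).
#' @param lf_amplitude,hf_amplitude Carrier amplitudes (a.u.).
#' @param phase_lag Phase lag psi between LF phase and envelope peak (rad).
#' @param mod_ratio Within-trial envelope modulation ratio (sideband/carrier
#'   amplitude, default 0.8); identical for both groups.
#' @param jitter_ms Half-range of the per-trial uniform latency jitter of the
#'   packet (default 10 ms; ignored in `"evoked"` phase mode).
#' @param taper_ms Width of the raised-cosine skirts placed outside the window
#'   (default 50 ms); wider skirts narrow the packet's spectral smear at the
#'   cost of partial-strength coupling bleeding into neighbouring latencies.
#' @return A `coupling_spec` object (field `construction` records the chosen
#'   injection).
#' @export
coupling_spec <- function(lf, hf, f_lf, f_hf, window_ms,
                          depth_patient, depth_control,
                          lf_amplitude = 1, hf_amplitude = 1, phase_lag = 0,
                          mod_ratio = 0.8, jitter_ms = 10, taper_ms = 50) {
  bands <- default_bands()
  names(bands) <- vapply(bands, `[[`, "", "name")
  for (nm in c(lf, hf)) {
    if (!nm %in% names(bands)) stop("unknown band name: ", nm)
  }
  if (f_lf < bands[[lf]]$f_low || f_lf > bands[[lf]]$f_high) {
    stop("f_lf outside its band")
  }
  if (f_hf < bands[[hf]]$f_low || f_hf > bands[[hf]]$f_high) {
    stop("f_hf outside its band")
  }
  construction <- if (f_hf + f_lf <= bands[[hf]]$f_high) {
    "ssb"
  } else if (f_hf + f_lf / 2 <= bands[[hf]]$f_high) {
    "beat"
  } else {
    stop(sprintf(
      "no band-limited injection possible: %s + %g Hz sideband leaves the %s band",
      hf, f_lf, hf))
  }
  stopifnot(depth_patient >= 0, depth_patient <= 1,
            depth_control >= 0, depth_control <= 1,
            length(window_ms) == 2L, window_ms[1L] < window_ms[2L],
            mod_ratio > 0, mod_ratio <= 1, jitter_ms >= 0)
  structure(
    list(lf = lf, hf = hf, f_lf = f_lf, f_hf = f_hf,
         window_ms = as.numeric(window_ms),
         depth_patient = depth_patient, depth_control = depth_control,
         lf_amplitude = lf_amplitude, hf_amplitude = hf_amplitude,
         phase_lag = phase_lag, construction = construction,
         mod_ratio = mod_ratio, jitter_ms = jitter_ms, taper_ms = taper_ms),
    class = "coupling_spec"
  )
}

#' Specify a synthetic oddball cohort
#'
#' Defines the study conditions emulated by the generator: an oddball-like
#' paradigm with 1 s epochs (-100..+900 ms around stimulus onset) at 1024 Hz,
#' 30 target trials per subject, 25 patients and 15 controls, ERP-like
#' deflections, 1/f background noise, and two group-dependent couplings --
#' theta -> beta1 in the slow-wave latency range (depth 0.8 patients vs 0.2
#' controls) and beta2 -> gamma around the N200 range (0.7 vs 0.2).
#'
#' @param n_patients,n_controls Group sizes (default 25 and 15).
#' @param n_trials Trials per subject (default 30).
#' @param fs Sampling rate in Hz (default 1024).
#' @param epoch_ms Epoch bounds in ms relative to onset (default
#'   `c(-100, 900)`).
#' @param couplings List of [coupling_spec()]; `NULL` for the two defaults.
#' @param erp_components Data frame with columns `latency_ms`, `width_ms`,
#'   `amplitude` describing Gaussian-windowed deflections; `NULL` for an
#'   N100/N200/P300/SW-like default set.
#' @param noise_exponent Spectral exponent of the 1/f background (default 1).
#' @param noise_rms Broadband RMS of the background noise (default 1.5).
#' @param depth_sd Between-subject SD of the coupling depth (default 0.05,
#'   clipped to `[0, 1]`).
#' @param phase_mode `"induced"` (default; LF and HF carrier phases random per
#'   trial, so coupling survives across-trial integration only through the
#'   envelope-phase relation) or `"evoked"` (carrier phases fixed across
#'   trials).
#' @param seed Integer seed for [simulate_cohort()].
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients = 25, n_controls = 15, n_trials = 30,
                        fs = 1024, epoch_ms = c(-100, 900), couplings = NULL,
                        erp_components = NULL, noise_exponent = 1,
                        noise_rms = 1.5, depth_sd = 0.05,
                        phase_mode = c("induced", "evoked"), seed = 1) {
  phase_mode <- match.arg(phase_mode)
  stopifnot(n_patients >= 2L, n_controls >= 2L, n_trials >= 2L, fs > 0,
            length(epoch_ms) == 2L, epoch_ms[1L] < epoch_ms[2L])
  if (is.null(couplings)) {
    couplings <- list(
      coupling_spec("theta", "beta1", f_lf = 7, f_hf = 13,
                    window_ms = c(780, 900),
                    depth_patient = 0.8, depth_control = 0.2,
                    lf_amplitude = 1.5, hf_amplitude = 2),
      coupling_spec("beta2", "gamma", f_lf = 24, f_hf = 31,
                    window_ms = c(220, 320),
                    depth_patient = 0.7, depth_control = 0.2,
                    hf_amplitude = 2)
    )
  }
  for (cp in couplings) {
    if (cp$window_ms[1L] < epoch_ms[1L] || cp$window_ms[2L] > epoch_ms[2L]) {
      stop("coupling window outside the epoch")
    }
  }
  if (is.null(erp_components)) {
    erp_components <- data.frame(
      latency_ms = c(100, 220, 330, 620),
      width_ms   = c(40, 50, 90, 200),
      amplitude  = c(-3, -2.5, 5, 2.5)
    )
  }
  structure(
    list(n_patients = n_patients, n_controls = n_controls,
         n_trials = n_trials, fs = fs, epoch_ms = as.numeric(epoch_ms),
         couplings = couplings, erp_components = erp_components,
         noise_exponent = noise_exponent, noise_rms = noise_rms,
         depth_sd = depth_sd, phase_mode = phase_mode, seed = seed),
    class = "cohort_spec"
  )
}

# 1/f^alpha noise by spectral shaping of white Gaussian noise, normalised to
# the requested broadband RMS.
pink_noise <- function(n, exponent = 1, rms = 1) {
  if (rms <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1e-12, seq_len(n - 1))          # zero the DC gain implicitly below
  f <- pmin(f, n - f)                    # two-sided frequency index
  gain <- f^(-exponent / 2)
  gain[1L] <- 0
  x <- Re(stats::fft(W * gain, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * rms
}

# Raised-cosine taper for a coupling packet. When the epoch leaves room on
# both sides, the window [start_ms, end_ms] is held at full strength and the
# ramps (ramp_ms) sit OUTSIDE it, keeping the packet's spectral smear narrow.
# When the window is pinned against the epoch end (no room for the trailing
# ramp), both ramps sit INSIDE the window instead: the packet then rises over
# the window's early portion and peaks over its late portion -- an
# end-of-epoch burst cannot be symmetric, and this concentrates full-strength
# coupling at the late latencies such windows are meant to represent.
window_taper <- function(latency_ms, start_ms, end_ms, ramp_ms = 50,
                         epoch_lo = min(latency_ms), epoch_hi = max(latency_ms)) {
  g <- numeric(length(latency_ms))
  g[latency_ms >= start_ms & latency_ms <= end_ms] <- 1
  len <- end_ms - start_ms
  room_hi <- epoch_hi - end_ms
  if (room_hi < ramp_ms) {
    # pinned to the epoch end: both ramps inside
    r_up <- min(ramp_ms, len / 2)
    up <- latency_ms >= start_ms & latency_ms < start_ms + r_up
    g[up] <- 0.5 * (1 - cos(pi * (latency_ms[up] - start_ms) / r_up))
    r_dn <- min(0.2 * len, room_hi + 0.2 * len)
    dn <- latency_ms > end_ms - r_dn & latency_ms <= end_ms
    g[dn] <- 0.5 * (1 - cos(pi * (end_ms - latency_ms[dn]) / r_dn))
    return(g)
  }
  r_lo <- min(ramp_ms, start_ms - epoch_lo)
  if (r_lo > 1) {
    up <- latency_ms >= start_ms - r_lo & latency_ms < start_ms
    g[up] <- 0.5 * (1 - cos(pi * (latency_ms[up] - (start_ms - r_lo)) / r_lo))
  } else {
    r_up <- 0.2 * len
    up <- latency_ms >= start_ms & latency_ms < start_ms + r_up
    g[up] <- 0.5 * (1 - cos(pi * (latency_ms[up] - start_ms) / r_up))
  }
  dn <- latency_ms > end_ms & latency_ms <= end_ms + ramp_ms
  g[dn] <- 0.5 * (1 - cos(pi * ((end_ms + ramp_ms) - latency_ms[dn]) / ramp_ms))
  g
}

#' Simulate one oddball epoch
#'
#' One trial is the sum of (i) Gaussian-windowed ERP-like deflections, (ii) for
#' each coupling, a smoothly tapered, latency-jittered packet containing a
#' low-frequency carrier plus high-frequency content whose band-limited
#' envelope follows `phi_LF - phase_lag - e_j` (see [coupling_spec()] for the
#' injection constructions and the phase-consistency depth semantics), and
#' (iii) 1/f background noise. The whole packet (both carriers) is confined to
#' its window so that concurrent couplings in other windows do not leak into
#' each other's bands. Carrier phases are randomised per trial in
#' `"induced"` mode, so only the phase relation between the LF carrier and the
#' HF envelope -- what the PAC estimator measures -- survives across-trial
#' integration. Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param spec A [cohort_spec()].
#' @param group `"patient"` or `"control"`.
#' @param depths Optional numeric vector of per-coupling modulation depths
#'   (e.g. subject-level depths); defaults to the group depths in `spec`.
#' @return Numeric vector of `round((epoch_ms[2] - epoch_ms[1]) / 1000 * fs)`
#'   samples.
#' @export
simulate_trial <- function(spec, group = c("patient", "control"),
                           depths = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  group <- match.arg(group)
  n <- round(diff(spec$epoch_ms) / 1000 * spec$fs)
  lat <- spec$epoch_ms[1L] + (seq_len(n) - 0.5) / spec$fs * 1000
  tt <- lat / 1000                                  # seconds post-onset
  x <- numeric(n)
  for (k in seq_len(nrow(spec$erp_components))) {
    e <- spec$erp_components[k, ]
    x <- x + e$amplitude *
      exp(-0.5 * ((lat - e$latency_ms) / (e$width_ms / 2))^2)
  }
  if (is.null(depths)) {
    depths <- vapply(spec$couplings, function(cp) {
      if (group == "patient") cp$depth_patient else cp$depth_control
    }, numeric(1L))
  }
  for (k in seq_along(spec$couplings)) {
    cp <- spec$couplings[[k]]
    m <- depths[k]
    if (spec$phase_mode == "induced") {
      phi0 <- stats::runif(1L, 0, 2 * pi)
      th0 <- stats::runif(1L, 0, 2 * pi)
      jit <- stats::runif(1L, -cp$jitter_ms, cp$jitter_ms)
      eps <- stats::runif(1L, -pi * (1 - m), pi * (1 - m))
    } else {
      phi0 <- 0
      th0 <- 0
      jit <- 0
      eps <- 0
    }
    # clip the jittered window to the epoch
    jit <- min(max(jit, spec$epoch_ms[1L] - cp$window_ms[1L]),
               spec$epoch_ms[2L] - cp$window_ms[2L])
    g <- window_taper(lat, cp$window_ms[1L] + jit, cp$window_ms[2L] + jit,
                      ramp_ms = cp$taper_ms,
                      epoch_lo = spec$epoch_ms[1L],
                      epoch_hi = spec$epoch_ms[2L])
    lf_phase <- 2 * pi * cp$f_lf * tt + phi0
    hf_phase <- 2 * pi * cp$f_hf * tt + th0
    lag <- cp$phase_lag + eps
    mod_phase <- if (cp$construction == "ssb") {
      lf_phase - lag
    } else {
      # random half-cycle flip: the envelope harmonic doubles the phase, so
      # the flip cancels there while decorrelating the half-rate fundamental
      # (whose half-angle phase would otherwise stay partially coherent with
      # the full-rate carriers) from every other band
      (lf_phase - lag) / 2 +
        if (spec$phase_mode == "induced") pi * stats::rbinom(1L, 1L, 0.5) else 0
    }
    # fixed-ratio two-tone packet, RMS-normalised: amplitude statistics are
    # identical across depths; only the phase-lag consistency differs
    x <- x + g * (cp$lf_amplitude * cos(lf_phase) +
      cp$hf_amplitude * sqrt(2 / (1 + cp$mod_ratio^2)) *
        (cos(hf_phase) + cp$mod_ratio * cos(hf_phase + mod_phase)))
  }
  x + pink_noise(n, spec$noise_exponent, spec$noise_rms)
}

#' Simulate a synthetic oddball cohort with ground-truth coupling
#'
#' Generates per-subject [trial_set()] objects under the study conditions of
#' `spec`. Each subject receives coupling depths jittered around the group
#' value (`depth_sd`, clipped to `[0, 1]`). The non-target condition, if
#' requested, is the same generator with all depths scaled by
#' `nontarget_scale` (default 0.25), emulating the weaker coupling of purely
#' evoked responses.
#'
#' @param spec A [cohort_spec()].
#' @param conditions Subset of `c("target", "nontarget")` (default target
#'   only).
#' @param nontarget_scale Depth multiplier for the non-target condition.
#' @return A `cfc_cohort`: list with `target` (list of trial sets, patients
#'   first), optionally `nontarget`, and `ground_truth` -- a data frame naming
#'   the coupled pairs, their windows, and the default-grid segments whose
#'   centres fall inside each window.
#' @export
simulate_cohort <- function(spec, conditions = "target",
                            nontarget_scale = 0.25) {
  stopifnot(inherits(spec, "cohort_spec"))
  conditions <- match.arg(conditions, c("target", "nontarget"),
                          several.ok = TRUE)
  n <- round(diff(spec$epoch_ms) / 1000 * spec$fs)
  onset_index <- round(-spec$epoch_ms[1L] / 1000 * spec$fs) + 1L
  groups <- c(rep("patient", spec$n_patients), rep("control", spec$n_controls))
  out <- stats::setNames(vector("list", length(conditions)), conditions)
  gt_grid <- segment_grid(n, spec$fs)
  with_seed(spec$seed, {
    subj_depths <- lapply(seq_along(groups), function(s) {
      base <- vapply(spec$couplings, function(cp) {
        if (groups[s] == "patient") cp$depth_patient else cp$depth_control
      }, numeric(1L))
      pmin(1, pmax(0, base + stats::rnorm(length(base), 0, spec$depth_sd)))
    })
    for (cond in conditions) {
      scale <- if (cond == "target") 1 else nontarget_scale
      out[[cond]] <- lapply(seq_along(groups), function(s) {
        dat <- t(vapply(seq_len(spec$n_trials), function(tr) {
          simulate_trial(spec, groups[s], depths = subj_depths[[s]] * scale)
        }, numeric(n)))
        trial_set(dat, spec$fs,
                  subject_id = sprintf("s%02d", s), group = groups[s],
                  condition = cond, onset_index = onset_index)
      })
    }
  })
  centers_post <- gt_grid$centers_ms + spec$epoch_ms[1L]
  gt <- do.call(rbind, lapply(spec$couplings, function(cp) {
    segs <- which(centers_post >= cp$window_ms[1L] &
                    centers_post <= cp$window_ms[2L])
    data.frame(lf = cp$lf, hf = cp$hf,
               window_start_ms = cp$window_ms[1L],
               window_end_ms = cp$window_ms[2L],
               first_segment = min(segs), last_segment = max(segs),
               depth_patient = cp$depth_patient,
               depth_control = cp$depth_control,
               stringsAsFactors = FALSE)
  }))
  structure(
    c(out, list(ground_truth = gt, spec = spec)),
    class = "cfc_cohort"
  )
}

#' @export
print.cfc_cohort <- function(x, ...) {
  cat(sprintf("<cfc_cohort: %d patients + %d controls, %d trials, conditions: %s>\n",
              x$spec$n_patients, x$spec$n_controls, x$spec$n_trials,
              paste(setdiff(names(x), c("ground_truth", "spec")),
                    collapse = ", ")))
  invisible(x)
}
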