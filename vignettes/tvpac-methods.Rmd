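---
title: "Time-varying phase-amplitude coupling biomarkers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-varying phase-amplitude coupling biomarkers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvpac)
```

## The problem

Event-related EEG responses carry information not only in their waveform
(the classical averaged evoked potential) but in transient interactions
*between* oscillatory components: the amplitude of a fast rhythm waxing and
waning with the phase of a slower one (phase-amplitude coupling, PAC, or
"nested oscillations"). `tvpac` estimates such coupling from multi-trial
single-sensor epochs, tracks it over latency, scores how well each
(rhythm-pair, latency) coupling separates two groups of subjects, and builds
a cross-validated linear-SVM biomarker from the most discriminative
couplings. A synthetic oddball-paradigm cohort generator with exact ground
truth closes the loop: every stochastic claim the package makes about its
estimators is tested against data whose coupling structure is known.

## The estimator

Seven canonical rhythm bands partition 2–45 Hz: delta 2–4, theta 4–8,
alpha1 8–10, alpha2 10–13, beta1 13–20, beta2 20–30, gamma 30–45 Hz.
For an ordered pair LF → HF the per-trial chain is:

1. band-pass the wide-band epoch into the LF and HF bands
   (3rd-order Butterworth, applied forward and backward so the phase
   response is exactly zero and the effective magnitude response is the
   squared single-pass response);
2. take the analytic signal (Hilbert transform) of both; keep the LF phase
   `phi_LF(t)` and the HF envelope `A_HF(t)`;
3. band-pass the (mean-subtracted) envelope within the LF band and
   Hilbert-transform again, extracting the phase `phi'(t)` of the LF-rate
   amplitude modulation;
4. form the wrapped phase differences `dphi(t) = phi_LF(t) - phi'(t)`.

If the HF envelope is modulated at a fixed lag behind the LF phase, `dphi`
is constant. The phase-locking value `PLV = |mean(exp(1i dphi))|` turns this
into a 0–1 index. Across trials, the time-varying PLV at latency `t` is the
modulus of the across-trial mean phasor; with few trials (~30 per subject
here) the estimate is stabilised by pooling trials *and* samples inside
non-overlapping 20 ms stepping windows. A 1 s epoch at 1024 Hz gives
`round(1024 / 20.48) = 50` segments of 20–21 samples — the boundaries are
spread by integer rounding so the windows tile the epoch exactly. Per
subject this yields a `[7 x 7 x 50]` tensor with the 21 LF → HF pairs in its
upper triangle (the diagonal and the HF → LF half are structurally zero).

Mean-subtracting the envelope before its second band-pass keeps the delta
LF band from being dominated by the envelope's DC component. The chain is
division-free, so trials without HF energy produce defined (null-level)
values rather than numerical blow-ups.

### Numerical choices

* Filters are designed per (band, sampling-rate) pair and cached. The
  transfer function from `signal::butter` is refactored into second-order
  sections by splitting at its poles; each biquad keeps the band-pass
  numerator `(1, 0, -1)` and the overall gain is applied once. This keeps
  forward-backward filtering linear to ~1e-13 even for the narrowest band
  (delta at 1024 Hz, pole radii up to 0.9977), where direct transfer-function
  evaluation loses 5–6 digits.
* Zero-phase mode = forward-backward filtering with odd-symmetric edge
  padding of three filter orders.
* The Hilbert transform is computed by FFT with mirror padding
  (`min(256, n/4)` samples per edge). By default the analytic signal is
  taken on the *concatenated* filtered recording (`hilbert = "concat"`),
  matching the concatenated filtering step: edge artifacts then exist only
  at the two ends of the whole recording. Per-trial transformation
  (`hilbert = "trial"`) is available for sensitivity analysis; it leaves a
  phase-estimation artifact in the first and last ~100–150 ms of *every*
  epoch, which measurably degrades late-latency couplings — the reason
  "concat" is the default.
* Trials are concatenated in stored order; seam discontinuities are
  accepted (their filter transients are local and group-symmetric).

## Feature scoring and the stability-weighted rank

Flattening each subject's tensor (21 pairs x 50 segments, canonical
lexicographic pair order) gives 1050 candidate features. Each feature is
scored by the absolute tie-corrected normal-approximation z of the
two-sample Wilcoxon rank-sum statistic (no continuity correction); being
rank-based, the score is invariant to any monotone rescaling of a feature.
Because a single small cohort makes such scores unstable, the cohort is
resampled with replacement 1000 times (class-stratified, preserving group
sizes — unstratified resampling can produce one-class replicates on which
the rank-sum is undefined; an unstratified mode exists behind a flag) and
each feature's stability-weighted score is

```
Wscore* = mean(bootstrap scores) / sd(bootstrap scores)
```

i.e. the inverse coefficient of variation over replicates (sample sd,
n-1 denominator). Features whose bootstrap score never varies are flagged
and ranked last rather than producing infinities. Ties in the ranking break
by higher bootstrap mean, then canonical feature order — a stable, fully
documented permutation. The top `p = 30` features feed the classifier;
`sweep_p()` traces the accuracy-vs-p curve that motivates that default.

The heavy loop is vectorised: per bootstrap replicate the rank-sum z of all
features is computed in one pass from precomputed per-column sort orders and
tie groups, with duplicated subjects and cross-subject value ties entering
the variance through the exact tie-corrected form
`Var(W) = n1 n2 / (N(N-1)) * sum_k c_k (r_k - (N+1)/2)^2`.

## Classification and leakage control

The biomarker is a linear SVM (cost C = 1) on z-scored selected features,
with scaling statistics always fit on the training fold only. Two
validation schemes are provided: leave-one-out over subjects, and repeated
(default 200x) class-stratified 35/5 splits whose metric means are
reported. Sensitivity is the detection rate of the patient group.

Feature selection placement is the critical honesty choice:

* `mode = "nested"` (default) reruns the bootstrap ranking *inside every
  training fold*, so the held-out subject never influences selection;
* `mode = "paper_faithful"` selects once on the full cohort before
  cross-validation — the historically common protocol. On label-permuted
  null data it is measurably optimistic (~0.75 vs ~0.38 accuracy in the
  packaged acceptance test), which is exactly the bias the nested mode
  removes.

A caveat documented by the test suite: on *null* data, nested LOOCV with
imbalanced classes lands below the majority-class rate, not at it — holding
out a patient leaves the training set relatively poorer in patients, and
selection on noise then tilts predictions against the held-out class
("anti-learning"). This pessimistic bias is the opposite direction from
leakage; the leakage guard therefore asserts that null accuracy does not
*exceed* chance, not two-sided equality.

## Contrast graphs

Group- or condition-averaged tensors are compared over deflection windows
(N100/N200/P300/slow-wave; defaults 80–140, 180–280, 280–450, 500–900 ms
post-onset — generic textbook latencies meant to be checked against the
grand average with `ga_extrema()`). A segment belongs to a window when its
centre does. Integrating PLV over the window's segments and forming
`(A - B) / B` per pair gives a directed graph of relative increase
(target vs non-target) or relative difference (patients vs controls;
positive = stronger coupling in patients). Zero-denominator entries are
flagged `NA` with a logged count, never silently infinite.

## The synthetic cohort generator

The generator emulates the structure the pipeline expects from an oddball
study: 25 patients + 15 controls, 30 target trials each, 1 s epochs
(-100..+900 ms) at 1024 Hz, ERP-like Gaussian deflections
(N100/N200/P300/SW analogues), 1/f background noise (spectral shaping of
white noise, exponent 1, broadband RMS 1.5), and two injected couplings:
theta → beta1 at 780–900 ms (depth 0.8 patients / 0.2 controls) and
beta2 → gamma at 220–320 ms (0.7 / 0.2), with subject-level depth jitter
(sd 0.05, clipped to [0, 1]). The non-target condition is the same
generator with depths scaled by 0.25.

Three design points matter and were driven by the estimator's physics:

* **Band-limited injection.** The estimator reads the envelope *after*
  band-pass filtering, so naive amplitude modulation of a pure carrier is
  invisible whenever the modulation sidebands fall outside the HF band —
  which they do for both default pairs. The packets are therefore built
  in-band: a single-sideband tone pair (`f_hf`, `f_hf + f_lf`; envelope
  `|1 + m e^{i phi}|`) when the sideband fits the band, and a deep-beat
  pair (tones `f_lf/2` apart, whose envelope rectification harmonic sits
  exactly at `f_lf`) when — as for beta2 → gamma, where `f_lf` exceeds the
  gamma band's width — no band-limited signal can carry first-order
  envelope modulation at `f_lf`. A per-trial random half-cycle flip on the
  beat's half-rate branch removes the residual 2/pi coherence that
  half-angle phases would otherwise retain with the full-rate carriers.
* **Depth = across-trial phase consistency.** Within every trial the
  envelope is modulated at a fixed ratio (0.8) and the packet is
  RMS-normalised; `depth` only controls the spread of the per-trial
  envelope lag (`uniform(+/- pi (1 - depth))`), whose across-trial PLV is
  `sin(pi(1-m)) / (pi(1-m))`. Groups differing only in depth therefore have
  *identical* amplitude, spectral and envelope-shape statistics — the group
  contrast is purely phase coupling, invisible in principle to
  amplitude-based representations. (An amplitude-scaled depth leaks a
  group difference into many estimator slots at once through envelope
  spectra, which is a different — and weaker — claim than PAC recovery.)
* **Latency jitter and tapering.** Packets are jittered by +/-10 ms per
  trial (induced bursts are not sample-locked; the injected coupling rides
  inside the packet and survives, while spurious evoked locking between
  the fixed ERP and a fixed burst edge does not) and tapered with 50 ms
  raised-cosine skirts placed *outside* the stated window, keeping coupling
  at full strength across the window while the packet's spectral smear
  stays narrow. A window pinned against the epoch end (the theta → beta1
  default) gets both ramps inside, concentrating full-strength coupling in
  its late portion.

The noise level (RMS 1.5 vs packet amplitudes 1.5–2) was fixed so that
single trials are noise-dominated, as in real recordings, while 30-trial
pooling resolves the injected contrast; at much lower noise every
packet-touched latency saturates the rank-sum and feature localisation
degenerates, at much higher noise the weaker beat coupling drowns.

What the generator does *not* emulate: biophysical neural mass dynamics,
multichannel volume conduction, non-stationary background spectra,
artifacts (beyond what the amplitude rejector exercises), or realistic
trial-to-trial ERP variability. A pipeline that passes these tests is
validated as an *estimator* — correctness on real recordings additionally
depends on all of the above.

## Problem sizes used by the packaged tests

The acceptance tests run the full stated design (25 + 15 subjects,
30 trials, bootstrap 200) for feature recovery across 20 generator seeds
and for leakage-controlled LOOCV across 10 seeds; the representation
comparison (coupling features vs time-locked averages, averaged
spectrograms and Morlet scalograms through the identical ranking and
classification stages) runs on a reduced cohort (12 + 8 subjects,
20 trials, bootstrap 100) over 10 seeds, with the Morlet scalogram
time-decimated (every 16th sample). These sizes are the package's choice of
a balance between statistical resolution and iteration speed; all of them
are parameters, not constants.

## Known limitations

* Only single-sensor epochs; no montage handling or artifact correction
  beyond amplitude thresholding.
* The canonical 3rd-order band-passes have gentle skirts: genuinely coupled
  content within ~4 Hz of a band edge bleeds an attenuated copy of its
  contrast into the neighbouring band's slots. This is a property of the
  estimator family itself, visible in the synthetic recovery tests.
* Phase-phase, power-power and phase-frequency coupling modes are out of
  scope, as is surrogate-based significance testing of individual PLV
  values (the pipeline ranks features; it does not test them).
* The repeated-split scheme reports means over repeats without a variance
  decomposition; fold-level detail is returned for callers who want one.
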