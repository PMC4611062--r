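test_that("cohort simulation is deterministic and matches its spec", {
  spec <- cohort_spec(seed = 31)
  co <- simulate_cohort(spec)
  expect_length(co$target, 40L)
  expect_true(all(vapply(co$target, function(t) all(dim(t$data) == c(30, 1024)),
                         logical(1))))
  expect_equal(sum(vapply(co$target, `[[`, "", "group") == "patient"), 25L)
  expect_equal(co$target[[1]]$onset_index, 103L)

  co2 <- simulate_cohort(spec)
  expect_identical(co$target[[5]]$data, co2$target[[5]]$data)
  co3 <- simulate_cohort(cohort_spec(seed = 32))
  expect_false(identical(co$target[[5]]$data, co3$target[[5]]$data))

  gt <- co$ground_truth
  expect_equal(gt$lf, c("theta", "beta2"))
  expect_equal(gt$hf, c("beta1", "gamma"))
  expect_equal(gt$window_start_ms, c(780, 220))

  tr1 <- tvpac:::with_seed(5, simulate_trial(spec, "patient"))
  tr2 <- tvpac:::with_seed(5, simulate_trial(spec, "patient"))
  expect_identical(tr1, tr2)
})

test_that("amplitude-threshold rejection drops exactly the spiked trials", {
  ts <- noise_trialset(n_trials = 8, seed = 2)
  expect_equal(reject_trials(ts, Inf)$data, ts$data)
  spiked <- ts
  spiked$data[3, 500] <- 10 * max(abs(ts$data))
  thr <- 2 * max(abs(ts$data))
  expect_message(out <- reject_trials(spiked, thr), "dropped 1")
  expect_equal(nrow(out$data), 7L)
  expect_equal(out$data, spiked$data[-3, ])
  expect_equal(attr(out, "n_rejected"), 1L)
  expect_lte(nrow(reject_trials(spiked, thr)$data), nrow(spiked$data))
  expect_error(reject_trials(ts, 1e-9), "all")
})

test_that("noise-free full-depth coupling reproduces its envelope model", {
  # deterministic (evoked) trial, single mid-epoch SSB coupling, no ERP/noise:
  # the beta1-band envelope must track 1 + cos(phi_LF - psi) inside the window
  # mid-band carriers (tones at 35 and 41 Hz, interior of the gamma band)
  # keep the band-pass from distorting the injected envelope shape
  spec <- cohort_spec(
    n_patients = 2, n_controls = 2, noise_rms = 0, depth_sd = 0,
    phase_mode = "evoked",
    couplings = list(coupling_spec("theta", "gamma", f_lf = 6, f_hf = 35,
                                   window_ms = c(300, 600),
                                   depth_patient = 1, depth_control = 1)),
    erp_components = data.frame(latency_ms = numeric(), width_ms = numeric(),
                                amplitude = numeric()),
    seed = 1)
  tr <- simulate_trial(spec, "patient")
  fs <- spec$fs
  lat <- -100 + (seq_along(tr) - 0.5) / fs * 1000
  env <- analytic(bandpass(tr, band_spec("gamma", 30, 45), fs))$amplitude
  w <- which(lat >= 330 & lat <= 570)
  target <- 1 + cos(2 * pi * 6 * lat / 1000)
  expect_gte(stats::cor(env[w], target[w]), 0.95)

  # beat construction: the gamma envelope, band-passed in the beta2 range,
  # must be phase-locked to the LF carrier
  spec_bg <- cohort_spec(
    n_patients = 2, n_controls = 2, noise_rms = 0, depth_sd = 0,
    phase_mode = "evoked",
    couplings = list(coupling_spec("beta2", "gamma", f_lf = 24, f_hf = 31,
                                   window_ms = c(300, 600),
                                   depth_patient = 1, depth_control = 1)),
    erp_components = data.frame(latency_ms = numeric(), width_ms = numeric(),
                                amplitude = numeric()),
    seed = 1)
  tr2 <- simulate_trial(spec_bg, "patient")
  b2 <- band_spec("beta2", 20, 30)
  gam <- band_spec("gamma", 30, 45)
  env2 <- analytic(bandpass(tr2, gam, fs))$amplitude
  envf <- bandpass(env2 - mean(env2), b2, fs)
  phi <- analytic(envf)$phase
  dphi <- wrap_phase(2 * pi * 24 * lat[w] / 1000 - phi[w])
  expect_gte(plv(dphi), 0.9)
})

test_that("coupled-window PLV exceeds outside-window PLV without noise", {
  # ERP-free: with zero noise any trial-invariant content is perfectly
  # phase-locked across trials, which would mask the comparison
  spec <- cohort_spec(
    n_patients = 2, n_controls = 2, n_trials = 20, noise_rms = 0,
    depth_sd = 0,
    couplings = list(coupling_spec("theta", "beta1", f_lf = 7, f_hf = 13,
                                   window_ms = c(300, 500),
                                   depth_patient = 0.8, depth_control = 0.8,
                                   lf_amplitude = 1.5, hf_amplitude = 2)),
    erp_components = data.frame(latency_ms = numeric(), width_ms = numeric(),
                                amplitude = numeric()),
    seed = 1)
  for (s in 1:5) {
    spec$seed <- 100 + s
    co <- simulate_cohort(spec)
    m <- pac_matrix(pac_tensor(co$target[[1]], bands = list(theta, beta1)))
    centers <- co$target[[1]]$grid
    inside <- mean(m[1, 22:29])    # segment centres ~320-480 ms post-onset
    outside <- mean(m[1, c(2:12, 36:48)])
    expect_gt(inside, outside)
  }
})

test_that("estimated coupling strength rises with depth", {
  # noise-free trials isolate the coupling-consistency mapping from
  # estimator noise; randomness is the per-trial phases/lags/jitter
  depths <- c(0, 0.25, 0.5, 0.75, 1)
  n_seeds <- 20
  spec <- cohort_spec(n_patients = 2, n_controls = 2, n_trials = 20,
                      noise_rms = 0, seed = 1)
  grid <- segment_grid(1024, 1024, 20)
  med <- vapply(depths, function(d) {
    vals <- vapply(seq_len(n_seeds), function(s) {
      ts <- tvpac:::with_seed(7000 + s, {
        dat <- t(vapply(seq_len(20), function(j) {
          simulate_trial(spec, "patient", depths = c(d, 0))
        }, numeric(1024)))
        trial_set(dat, 1024, onset_index = 103L)
      })
      m <- pac_matrix(pac_tensor(ts, bands = list(theta, beta1)))
      mean(m[1, 45:50])
    }, numeric(1))
    stats::median(vals)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
  expect_gt(med[5], med[1] + 0.3)
})

test_that("the max-coupling profile peaks inside an injected window", {
  spec <- cohort_spec(n_patients = 2, n_controls = 2, seed = 77)
  co <- simulate_cohort(spec)
  pt <- pac_tensor(co$target[[1]])       # a patient: depths 0.8 / 0.7
  prof <- summarize_profiles(pt)
  peak_ms <- pt$grid$centers_ms[which.max(prof$max)] - 100
  gt <- co$ground_truth
  in_win <- any(peak_ms >= gt$window_start_ms - 10 &
                peak_ms <= gt$window_end_ms + 10)
  expect_true(in_win)
})
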