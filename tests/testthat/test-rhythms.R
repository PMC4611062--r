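test_that("default band catalogue is the canonical 7-rhythm partition", {
  b <- default_bands()
  expect_length(b, 7L)
  expect_equal(b[[1]]$name, "delta")
  expect_equal(c(b[[1]]$f_low, b[[1]]$f_high), c(2, 4))
  expect_equal(b[[7]]$name, "gamma")
  expect_equal(c(b[[7]]$f_low, b[[7]]$f_high), c(30, 45))
  # contiguous, non-overlapping partition of 2-45 Hz
  for (k in 1:6) expect_equal(b[[k]]$f_high, b[[k + 1]]$f_low)
  expect_true(all(diff(vapply(b, `[[`, 0, "f_low")) > 0))
})

test_that("band-pass matches the analytic squared Butterworth response", {
  fs <- 1024
  t <- (0:4095) / fs
  flt <- signal::butter(3, c(4, 8) / (fs / 2), type = "pass")
  Hsq <- function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    Mod(sum(flt$b * z^(0:6)) / sum(flt$a * z^(0:6)))^2
  }
  interior <- 1000:3000
  for (f in c(6, 50)) {
    y <- bandpass(sin(2 * pi * f * t), theta, fs)
    gain <- max(abs(y[interior]))
    expect_equal(gain, Hsq(f), tolerance = 0.02)
  }
  expect_gte(max(abs(bandpass(sin(2 * pi * 6 * t), theta, fs)[interior])), 0.90)
  expect_lte(max(abs(bandpass(sin(2 * pi * 50 * t), theta, fs)[interior])), 0.01)
})

test_that("band-pass is linear, zero-phase, and rejects bad inputs", {
  fs <- 512
  x <- tvpac:::with_seed(1, rnorm(2048))
  y <- tvpac:::with_seed(2, rnorm(2048))
  lhs <- bandpass(2 * x - 3 * y, theta, fs)
  rhs <- 2 * bandpass(x, theta, fs) - 3 * bandpass(y, theta, fs)
  expect_lt(max(abs(lhs - rhs)), 1e-10)
  expect_equal(bandpass(numeric(2048), theta, fs), numeric(2048))

  # zero-phase: cross-correlation between a band-limited input and its
  # re-filtered version peaks at lag 0
  bl <- bandpass(x, theta, fs)
  cc <- stats::ccf(bandpass(bl, theta, fs), bl, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_error(bandpass(x, band_spec("bad", 100, 300), fs), "Nyquist")
  expect_error(bandpass(x[1:10], theta, fs), "too short")
})

test_that("filter_trialset equals segmenting the filtered concatenation", {
  ts <- noise_trialset(n_trials = 4, n_samples = 512, fs = 512)
  out <- filter_trialset(ts, theta)
  expect_equal(dim(out$data), dim(ts$data))
  manual <- bandpass(as.vector(t(ts$data)), theta, ts$fs)
  expect_equal(as.vector(t(out$data)), manual, tolerance = 1e-12)

  one <- trial_set(ts$data[1, , drop = FALSE], ts$fs, onset_index = 103L)
  expect_equal(as.vector(filter_trialset(one, theta)$data),
               bandpass(ts$data[1, ], theta, ts$fs))
})

test_that("seam-matched periodic trials filter like the periodic long signal", {
  fs <- 1024
  n <- 1024
  # 6 Hz completes 6 full cycles per 1024-sample trial, so identical
  # concatenated trials are phase-continuous at every seam; away from the
  # recording ends (filter ring-down ~ a few hundred samples) all trials must
  # therefore be filtered identically, as one periodic long signal would be.
  tr <- sin(2 * pi * 6 * (0:(n - 1)) / fs)
  ts <- trial_set(matrix(rep(tr, 10), 10, byrow = TRUE), fs, onset_index = 103L)
  f <- filter_trialset(ts, theta)
  expect_lt(max(abs(f$data[5, ] - f$data[6, ])), 1e-6)
  # and the middle trials match the exact periodic steady state |H|^2 sin
  flt <- tvpac:::butter_band(theta, fs)
  z <- exp(-1i * 2 * pi * 6 / fs)
  gain2 <- Mod(sum(flt$b * z^(0:6)) / sum(flt$a * z^(0:6)))^2
  expect_lt(max(abs(f$data[5, ] - gain2 * tr)), 1e-6)
})

test_that("analytic signal recovers envelope and phase of a cosine", {
  fs <- 1024
  x <- cos(2 * pi * 8 * (0:1023) / fs)
  a <- analytic(x)
  interior <- 100:900
  expect_true(all(abs(a$amplitude[interior] - 1) <= 0.02))

  up <- cumsum(c(a$phase[1], wrap_phase(diff(a$phase))))
  slope <- stats::coef(stats::lm(up[interior] ~ I(interior / fs)))[[2]]
  expect_equal(slope, 2 * pi * 8, tolerance = 0.01)

  r <- tvpac:::with_seed(5, rnorm(300))
  expect_true(all(analytic(r)$amplitude >= 0))
  expect_error(analytic(c(1, NA, 3, 4)), "finite")
})

test_that("phase wrapping lands in (-pi, pi]", {
  x <- c(0, pi, -pi, 3 * pi, -2.5 * pi, 7)
  w <- wrap_phase(x)
  expect_true(all(w > -pi & w <= pi))
  expect_equal(exp(1i * w), exp(1i * x), tolerance = 1e-12)
  expect_equal(wrap_phase(pi), pi)
})
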