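fs_acq <- 8.138

sine_series <- function(f, dur = 2000, fs = fs_acq, amp = 1) {
  t <- seq(0, dur, by = 1 / fs)
  hemo_series(matrix(amp * sin(2 * pi * f * t), ncol = 1), fs = fs, channels = "Ch01")
}

test_that("resampling preserves duration and in-band amplitude", {
  h <- sine_series(0.02, dur = 600)
  r <- resample_series(h, 2)
  expect_equal(nrow(r$hbo), 600 * 2 + 1, tolerance = 1, ignore_attr = TRUE)
  t2 <- seq(0, by = 0.5, length.out = nrow(r$hbo))
  mid <- seq(round(length(t2) * 0.25), round(length(t2) * 0.75))
  expect_equal(ls_amplitude(r$hbo[mid, 1], t2[mid], 0.02), 1, tolerance = 0.01)
})

test_that("resampling leaves a DC series constant and rejects upsampling", {
  h <- hemo_series(matrix(3.2, 500, 1), fs = fs_acq, channels = "Ch01")
  r <- resample_series(h, 2)
  expect_equal(max(abs(r$hbo - 3.2)), 0, tolerance = 1e-9)
  expect_error(resample_series(r, 8), "upsampling")
})

test_that("mid-band sinusoids pass the filter with zero lag and >= 90% amplitude", {
  h <- sine_series(0.02, dur = 3000, fs = 2)
  f <- bandpass_series(h)
  t <- seq(0, by = 0.5, length.out = nrow(f$hbo))
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  expect_gte(ls_amplitude(f$hbo[mid, 1], t[mid], 0.02), 0.9)
  cc <- ccf(f$hbo[mid, 1], h$hbo[mid, 1], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("DC offsets are rejected by the band-pass", {
  h <- hemo_series(matrix(5, 3000, 1), fs = 2, channels = "Ch01")
  f <- bandpass_series(h)
  expect_lt(abs(mean(f$hbo)), 1e-3)
})

test_that("0.3 Hz attenuation matches the squared Butterworth magnitude response", {
  h <- sine_series(0.3, dur = 3000, fs = 2)
  f <- bandpass_series(h)
  t <- seq(0, by = 0.5, length.out = nrow(f$hbo))
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  measured <- ls_amplitude(f$hbo[mid, 1], t[mid], 0.3)
  bp <- signal::butter(3, c(0.005, 0.05), type = "pass")
  z <- exp(1i * pi * 0.3) # 0.3 Hz at fs = 2 -> normalized w = 0.3*pi
  H <- sum(bp$b * z^(0:(length(bp$b) - 1))) / sum(bp$a * z^(0:(length(bp$a) - 1)))
  expect_equal(measured, Mod(H)^2, tolerance = 0.05)
  expect_lte(measured, 0.1) # >= 90% stopband attenuation
})

test_that("band edges outside Nyquist are rejected", {
  h <- sine_series(0.02, dur = 100, fs = 2)
  expect_error(bandpass_series(h, 0.005, 1.2), "Nyquist")
  expect_error(bandpass_series(h, 0, 0.05), "Nyquist")
})

test_that("resample then band-pass reproduces an in-band analytic signal", {
  f0 <- 0.02
  h <- sine_series(f0, dur = 2400)
  r <- bandpass_series(resample_series(h, 2))
  t <- seq(0, by = 0.5, length.out = nrow(r$hbo))
  keep <- t > 400 & t < max(t) - 400 # 2 filter time constants (1/0.005 s) per edge
  err <- r$hbo[keep, 1] - sin(2 * pi * f0 * t[keep])
  expect_lt(sqrt(mean(err^2)) / sqrt(0.5), 0.02) # RMS relative to signal RMS
})

test_that("epoching yields one baseline-zero epoch per trial and drops short windows", {
  sch <- generate_paradigm(3, order_seed = 1)
  hemo <- simulate_hemodynamics(sch, seed = 9)
  filt <- bandpass_series(resample_series(hemo))
  ep <- epoch_and_baseline(filt, sch)
  expect_equal(dim(ep$data), c(124, 15, 6))
  expect_equal(as.vector(table(ep$index$condition)), c(3, 3))
  bl <- ep$times >= -1 & ep$times < 0
  expect_lt(max(abs(apply(ep$data[bl, , , drop = FALSE], c(2, 3), mean))), 1e-12)
})

test_that("trials without a full window are dropped with a reason", {
  sch <- generate_paradigm(2, order_seed = 1, lead_in = 0) # first onset at 0.5 s
  hemo <- simulate_hemodynamics(sch, seed = 9, tail = 0)   # last epoch also clipped
  filt <- resample_series(hemo)
  expect_message(ep <- epoch_and_baseline(filt, sch), "dropped")
  expect_lt(dim(ep$data)[3], nrow(sch$trials))
  expect_gte(nrow(ep$dropped), 1)
  expect_true(all(nchar(ep$dropped$reason) > 0))
})

test_that("a record covering no trial raises an empty-set error", {
  sch <- generate_paradigm(2, order_seed = 1)
  short <- hemo_series(matrix(rnorm(20), ncol = 1), fs = 2, channels = "Ch01")
  expect_error(suppressMessages(epoch_and_baseline(short, sch)), "no trial")
})
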