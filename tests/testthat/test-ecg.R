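# ECG preprocessing: filters, R-peak detection, autocorrelation period
# estimation, heartbeat relocation, and trace rendering.

fs <- 2000

test_that("notch filter removes 50 Hz and preserves the passband", {
  t <- seq_len(2 * fs) / fs
  hum <- ecg_record(sin(2 * pi * 50 * t), fs)
  out <- apply_notch(hum)
  # FFT-magnitude oracle at 50 Hz before/after
  expect_lte(rms_at_freq(out$samples, fs, 50),
             0.1 * rms_at_freq(hum$samples, fs, 50))

  low <- ecg_record(sin(2 * pi * 10 * t), fs)
  out_low <- apply_notch(low)
  expect_lt(abs(rms_at_freq(out_low$samples, fs, 10) /
                  rms_at_freq(low$samples, fs, 10) - 1), 0.05)

  zero <- ecg_record(rep(0, 2 * fs), fs)
  expect_equal(apply_notch(zero)$samples, rep(0, 2 * fs))
  expect_error(apply_notch(ecg_record(rnorm(100), fs = 80)),
               class = "stressfuse_invalid_config")
})

test_that("band-pass attenuates out-of-band tones and keeps in-band ones", {
  t <- seq_len(4 * fs) / fs
  mid <- 1001:7000   # avoid filter edge transients when measuring
  hf <- ecg_record(sin(2 * pi * 100 * t), fs)
  expect_lte(sd(apply_bandpass(hf)$samples[mid]), 0.1 * sd(hf$samples[mid]))
  inband <- ecg_record(sin(2 * pi * 10 * t), fs)
  expect_lt(abs(sd(apply_bandpass(inband)$samples[mid]) /
                  sd(inband$samples[mid]) - 1), 0.1)
  zero <- ecg_record(rep(0, fs), fs)
  expect_equal(apply_bandpass(zero)$samples, rep(0, fs))
  expect_error(apply_bandpass(ecg_record(rnorm(100), fs), low = 60, high = 50),
               class = "stressfuse_invalid_config")
})

test_that("filters are linear and length-preserving", {
  x <- with_seed(3, rnorm(2 * fs))
  y <- with_seed(4, rnorm(2 * fs))
  a <- 2.5; b <- -1.2
  for (f in list(apply_notch, apply_bandpass)) {
    lhs <- f(ecg_record(a * x + b * y, fs))$samples
    rhs <- a * f(ecg_record(x, fs))$samples + b * f(ecg_record(y, fs))$samples
    expect_equal(length(lhs), 2 * fs)
    expect_lt(max(abs(lhs - rhs)), 1e-8)
  }
})

test_that("standardization gives z-scores, scale invariance and idempotence", {
  r <- ecg_record(c(1, 2, 3, 5, 8, 13) * 1.0, fs)
  z <- standardize(r)
  expect_equal(mean(z$samples), 0)
  expect_equal(sd(z$samples), 1)
  expect_equal(standardize(ecg_record(5 * r$samples, fs))$samples, z$samples)
  expect_equal(standardize(z)$samples, z$samples)
  expect_error(standardize(ecg_record(rep(2, 100), fs)),
               class = "stressfuse_degenerate_input")
})

test_that("R-peak detection finds constructed maxima and rejects flat input", {
  rec <- peaks_record(c(1000, 2600, 4200), n = 6000)
  pk <- detect_r_peaks(rec, threshold_frac = 0.5)
  expect_equal(pk$indices, c(1000L, 2600L, 4200L))

  noisy <- peaks_record(c(1000, 2600, 4200), n = 6000, noise_sd = 0.05, seed = 2)
  pk2 <- detect_r_peaks(noisy, threshold_frac = 0.5)
  # oracle: argmax within +-50 samples of each true position
  truth <- vapply(c(1000, 2600, 4200), function(p) {
    win <- (p - 50):(p + 50)
    win[which.max(noisy$samples[win])]
  }, numeric(1))
  expect_equal(length(pk2$indices), 3L)
  expect_equal(as.numeric(pk2$indices), truth)
  expect_true(all(abs(pk2$indices - c(1000, 2600, 4200)) <= 5))

  expect_error(detect_r_peaks(ecg_record(rep(0, 6000), fs)),
               class = "stressfuse_empty_result")
})

test_that("short-time autocorrelation matches brute force and normalizes", {
  # impulse train with period 40
  x <- rep(0, 400); x[seq(1, 400, by = 40)] <- 1
  ac <- short_time_autocorr(x, max_lag = 120)
  expect_equal(ac$acf, acf_brute(x, 120), tolerance = 1e-10)
  expect_equal(ac$acf[1], 1)
  for (lag in c(40, 80))   # local maxima at the period multiples
    expect_true(ac$acf[lag + 1] > ac$acf[lag] &&
                  ac$acf[lag + 1] > ac$acf[lag + 2])
  expect_equal(which.max(ac$acf[2:121]) + 0, 40)          # lag-40 maximum

  wn <- with_seed(8, rnorm(2000))
  acw <- short_time_autocorr(wn, max_lag = 100)
  expect_equal(acw$acf, acf_brute(wn, 100), tolerance = 1e-9)
  expect_lt(max(abs(acw$acf[-1])), 3 / sqrt(2000) * 3)

  expect_error(short_time_autocorr(rnorm(10), max_lag = 10),
               class = "stressfuse_invalid_config")
})

test_that("clipping follows the printed piecewise formula exactly", {
  expect_equal(clip_autocorr(c(0.5, 0.05, -0.3)), c(0.4, 0, -0.2))
  expect_identical(clip_autocorr(c(0.1, -0.1, 0, 0.09)), rep(0, 4))
  for (s in 1:25) {
    x <- with_seed(s, runif(40, -1, 1))
    expect_identical(clip_autocorr(x), clip_brute(x))
  }
  # monotone: x <= y elementwise implies clip(x) <= clip(y)
  x <- with_seed(50, runif(100, -1, 1))
  y <- x + with_seed(51, runif(100, 0, 0.5))
  expect_true(all(clip_autocorr(x) <= clip_autocorr(y)))
  expect_error(clip_autocorr(x, alpha = -0.2, beta = 0.2),
               class = "stressfuse_invalid_config")
})

test_that("period estimation selects the first harmonic, not its double", {
  cl <- rep(0, 120); cl[41] <- 0.5   # single peak at lag 40
  expect_equal(estimate_rr_interval(cl), 40L)

  # periodic signal with period 50, max_lag covering 2 periods
  x <- rep(0, 600); x[seq(10, 600, by = 50)] <- 1
  ac <- short_time_autocorr(x, max_lag = 130)
  expect_equal(estimate_rr_interval(ac), 50L)

  expect_error(estimate_rr_interval(c(1, rep(0, 50))),
               class = "stressfuse_period_not_found")
})

test_that("relocation arithmetic and containment hold on synthetic beats", {
  # strictly periodic beats, period 1600 (75 bpm)
  pos <- seq(1000, 19000, by = 1600)
  rec <- peaks_record(pos, n = 20000)
  pk <- detect_r_peaks(rec)
  interior <- pk$indices[pk$indices > 4000 & pk$indices < 16000]
  pk$indices <- interior
  seg <- relocate_heartbeat(rec, pk)
  expect_equal(seg$start_index, interior[1] - floor(seg$t1 / 2))
  expect_equal(seg$end_index,
               interior[length(interior)] + floor(seg$t2 / 2))
  expect_lt(abs(seg$t1 - 1600), 20)
  expect_lt(abs(seg$t2 - 1600), 20)
  # boundaries at true inter-beat midpoints within 20 samples
  expect_lt(abs(seg$start_index - (interior[1] - 800)), 20)
  # every retained peak is inside the segment
  expect_true(all(seg$r_peaks >= 1 & seg$r_peaks <= length(seg$samples)))
  expect_error(relocate_heartbeat(rec, list(indices = c(100L))),
               class = "stressfuse_context_too_short")
})

test_that("trace rendering is deterministic with the configured geometry", {
  g <- gen_ecg(synth_config(), "calm", seed = 5)
  pp <- preprocess_ecg(g$record)
  expect_equal(dim(pp$image), c(230, 307))
  expect_true(all(pp$image >= 0 & pp$image <= 1))
  img2 <- render_ecg_image(pp$segment)
  expect_identical(pp$image, img2)
  flat <- render_ecg_image(list(samples = rep(1, 100)), width = 50, height = 40)
  expect_equal(sum(rowSums(flat) > 0), 1)   # single horizontal line
  expect_error(render_ecg_image(list(samples = numeric(0))),
               class = "stressfuse_degenerate_input")
})
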