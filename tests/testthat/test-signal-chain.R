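test_that("chip waveform places 1 ms rectangular pulses with oracle amplitudes", {
  p <- build_protocol()
  s <- knob_settings(20, 65)
  cal <- crir_calibration()
  cw <- synthesize_chip_waveform(p, s, calibration = cal)
  meta <- wave_meta(cw)
  expect_true(all(cw$v_chip >= 0))
  # each pulse is pulse_duration wide at the sampling grid
  params <- knob_to_params(s, calibration = cal)
  for (i in seq_len(nrow(meta$pulses))) {
    pl <- meta$pulses[i, ]
    idx <- which(cw$time >= pl$time - 1e-9 & cw$time < pl$time + 1e-3 - 1e-9)
    expect_identical(length(idx), 5L)  # 1 ms at 5 kHz
    expect_equal(unique(cw$v_chip[idx]), transfer_voltage(pl$luminance, params))
  }
  # zero outside all pulses
  in_pulse <- rep(FALSE, nrow(cw))
  for (i in seq_len(nrow(meta$pulses))) {
    in_pulse <- in_pulse | (cw$time >= meta$pulses$time[i] - 1e-9 &
                              cw$time < meta$pulses$time[i] + 1e-3 + 1e-9)
  }
  expect_true(all(cw$v_chip[!in_pulse] == 0))
})

test_that("chip configuration constraints are enforced", {
  expect_error(chip_config(pulse_duration = 3e-3), "0.1, 2")
  expect_error(chip_config(working_frequency = 25), "1, 20")
})

test_that("corneal coupling is charge-balanced, linear, and peak-calibrated", {
  p <- build_protocol(1000, 1000, 0.5, inter_step_interval = 4)
  s <- knob_settings(0, 65)  # saturated at 1000 cd/m2
  cal <- crir_calibration()
  cw <- synthesize_chip_waveform(p, s, calibration = cal)
  cor <- couple_to_cornea(cw)
  # long-window integral of the biphasic response tends to zero
  expect_lt(abs(sum(cor$v_cornea) / 5000), 1e-6 * max(abs(cor$v_cornea)))
  # peak equals attenuation x pulse amplitude
  amp <- max(cw$v_chip)
  expect_equal(max(cor$v_cornea), cal$coupling_atten * amp, tolerance = 1e-9)
  # biphasic: an opposite-sign overshoot after pulse offset
  expect_lt(min(cor$v_cornea), -0.1 * max(cor$v_cornea))
  # linearity: doubling the pulse amplitude doubles the corneal response
  cw2 <- cw
  cw2$v_chip <- 2 * cw$v_chip
  attr(cw2, "meta") <- wave_meta(cw)
  cor2 <- couple_to_cornea(cw2)
  expect_equal(cor2$v_cornea, 2 * cor$v_cornea, tolerance = 1e-12)
  # positive charge per pulse is reported
  expect_true(all(wave_meta(cor)$pulses$q_chip > 0))
})

test_that("corneal amplitude stays below 35 mV over the whole knob grid", {
  cal <- crir_calibration()
  grid <- knob_to_params(v_gl = rep(0:99, each = 100),
                         v_bias = rep(0:99, times = 100), calibration = cal)
  # corneal peak at saturating luminance is attenuation x v_max (closed form)
  peaks <- cal$coupling_atten * grid$v_max
  expect_lte(max(peaks), 0.035 + 1e-12)
  # and 35 mV x gain 10 leaves headroom below the 0.5 V rails
  cfg <- recording_config()
  expect_lt(max(peaks) * cfg$amp_gain, cfg$input_range)
})

test_that("digitizer applies gain, clips at the rails and quantizes to 1/2 LSB", {
  cfg <- quiet_config()
  p <- build_protocol(1000, 1000, 0.5)
  cw <- synthesize_chip_waveform(p, knob_settings(0, 65))
  cor <- couple_to_cornea(cw)
  dig <- amplify_and_digitize(cor, cfg)
  lsb_in <- 2 * cfg$input_range / 2^cfg$adc_bits / cfg$amp_gain
  expect_lte(max(abs(dig$voltage - cor$v_cornea)), lsb_in / 2 + 1e-15)
  expect_false(any(dig$clipped))
  expect_false(wave_meta(dig)$clipped_any)
  # zero input maps to the zero code
  zero <- cor
  zero$v_cornea <- numeric(nrow(zero))
  attr(zero, "meta") <- wave_meta(cor)
  expect_true(all(amplify_and_digitize(zero, cfg)$voltage == 0))
  # input above the rail-referred 50 mV produces flagged ceiling samples
  big <- cor
  big$v_cornea <- cor$v_cornea * 3  # peak ~105 mV -> 1.05 V after gain
  attr(big, "meta") <- wave_meta(cor)
  digb <- amplify_and_digitize(big, cfg)
  expect_true(any(digb$clipped))
  expect_gte(max(digb$voltage), cfg$input_range / cfg$amp_gain - lsb_in - 1e-12)
  expect_lte(max(digb$voltage), cfg$input_range / cfg$amp_gain)
})

test_that("realized band-pass hits its -3 dB points within 2%", {
  filt <- design_bessel_bandpass(0.312, 300, 5000)
  cut <- measure_cutoffs(filt)
  expect_equal(cut[["low"]], 0.312, tolerance = 0.02)
  expect_equal(cut[["high"]], 300, tolerance = 0.02)
  expect_error(design_bessel_bandpass(0.312, 3000, 5000), "Nyquist")
})

test_that("band-pass rejects DC after settling", {
  cfg <- quiet_config()
  x <- rep(1, 5000 * 30)
  y <- bessel_bandpass(x, cfg)
  expect_lt(max(abs(tail(y, 5000))), 1e-3)
})

test_that("recursive filter matches convolution with the analytic impulse response", {
  # at fine sampling, where discretizing the 1 ms pulse and the impulse
  # response is innocuous, the recursive realization must match direct
  # convolution with the sampled analytic impulse response within 1% peak
  # error
  fs <- 50000
  cfg <- quiet_config(sampling_rate = fs)
  n <- 25000
  x <- numeric(n)
  x[2501:(2501 + round(1e-3 * fs) - 1)] <- 1  # 1 ms rectangular test pulse
  y_digital <- bessel_bandpass(x, cfg)
  t <- (seq_len(n) - 1) / fs
  h <- analog_bandpass_impulse(cfg$f_low, cfg$f_high, fs, t)
  y_conv <- stats::convolve(x, rev(h), type = "open")[seq_len(n)] / fs
  peak <- max(abs(y_digital))
  expect_lt(max(abs(y_digital - y_conv)) / peak, 0.01)
  # at the acquisition rate of 5 kHz the same comparison is limited by
  # sampling the fast-rising impulse response; the response peak still
  # agrees to a few percent
  cfg5 <- quiet_config()
  n5 <- 2500
  x5 <- numeric(n5)
  x5[251:255] <- 1
  y5 <- bessel_bandpass(x5, cfg5)
  h5 <- analog_bandpass_impulse(cfg5$f_low, cfg5$f_high, 5000,
                                (seq_len(n5) - 1) / 5000)
  y5c <- stats::convolve(x5, rev(h5), type = "open")[seq_len(n5)] / 5000
  expect_lt(abs(max(abs(y5)) - max(abs(y5c))) / max(abs(y5)), 0.05)
})

test_that("filtered pulse is biphasic, delayed and broadened", {
  cfg <- quiet_config()
  p <- build_protocol(1000, 1000, 0.5)
  tr <- simulate_recording(p, knob_settings(0, 65), config = cfg)
  cw <- synthesize_chip_waveform(p, knob_settings(0, 65))
  onset <- wave_meta(cw)$pulses$time[1]
  win <- which(tr$time >= onset - 0.005 & tr$time <= onset + 0.05)
  v <- tr$voltage[win]
  t <- tr$time[win]
  # dominant positive first lobe followed by a negative lobe
  expect_gt(max(v), 0)
  expect_lt(min(v), 0)
  expect_gt(max(v), abs(min(v)))
  expect_lt(t[which.max(v)], t[which.min(v)])
  # delay: the filtered peak comes after the (instantaneous) corneal peak
  delay <- t[which.max(v)] - onset
  expect_gt(delay, 0)
  # broadening: the biphasic response outlasts the 1 ms pulse
  width <- diff(range(t[abs(v) > 0.1 * max(abs(v))]))
  expect_gt(width, 1e-3)
})

test_that("noise is seeded and reproducible; zero noise is a no-op", {
  p <- build_protocol(1, 10, 0.5)
  cfgA <- recording_config(noise_rms = 20e-6, seed = 123)
  t1 <- simulate_recording(p, config = cfgA)
  t2 <- simulate_recording(p, config = cfgA)
  expect_identical(t1$voltage, t2$voltage)
  t3 <- simulate_recording(p, config = recording_config(noise_rms = 20e-6,
                                                        seed = 124))
  expect_false(identical(t1$voltage, t3$voltage))
  cw <- synthesize_chip_waveform(p)
  cor <- couple_to_cornea(cw)
  same <- add_noise_and_artifacts(cor, quiet_config())
  expect_identical(same$v_cornea, cor$v_cornea)
})

test_that("artifact injection is labeled in the metadata", {
  p <- build_protocol(1, 10, 0.5)
  arts <- list(list(type = "blink", time = 1.0, duration = 0.2,
                    amplitude = 2e-3),
               list(type = "dropout", time = 3.0, duration = 0.1))
  tr <- simulate_recording(p, config = quiet_config(), artifacts = arts)
  aw <- wave_meta(tr)$artifact_windows
  expect_identical(nrow(aw), 2L)
  expect_setequal(aw$type, c("blink", "dropout"))
  cw <- synthesize_chip_waveform(p)
  cor <- couple_to_cornea(cw)
  expect_error(add_noise_and_artifacts(cor, quiet_config(),
                                       list(list(type = "sneeze", time = 1,
                                                 duration = 1))),
               "unknown artifact")
})

test_that("end-to-end response is linear in chip amplitude below clipping", {
  p <- build_protocol(1000, 1000, 0.5)
  scales <- c(0.2, 0.4, 0.6, 0.8, 1)
  peaks <- vapply(scales, function(sc) {
    tr <- simulate_recording(p, knob_settings(0, 65), config = quiet_config(),
                             output_scale = sc)
    max(tr$voltage)
  }, numeric(1))
  fit <- stats::lm(peaks ~ scales)
  expect_gt(summary(fit)$r.squared, 0.999)
  expect_equal(peaks[5] / peaks[1], 5, tolerance = 0.01)
})
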