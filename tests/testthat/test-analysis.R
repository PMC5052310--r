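test_that("noiseless simulated trace yields all expected pulses, unflagged", {
  tr <- simulate_recording(config = quiet_config())
  m <- detect_pulses(tr)
  expect_identical(nrow(m), 18L)  # 2 pulses x 9 steps at phase 0
  expect_false(any(m$artifact))
  expect_false(any(m$clipped))
  expect_false(any(m$low_snr))
  expect_true(all(m$amplitude > 0))
  # peaks are found near the expected onsets, shifted by the filter delay
  shift <- m$pulse_time - m$expected_time
  expect_true(all(shift > 0 & shift < 0.01))
  # amplitudes increase with luminance
  per_step <- tapply(m$amplitude, m$step, mean)
  expect_true(all(diff(per_step) > 0))
})

test_that("a device-off trace is reported as all low SNR, not dropped", {
  tr <- simulate_recording(output_scale = 0,
                           config = recording_config(noise_rms = 20e-6))
  m <- detect_pulses(tr)
  expect_identical(nrow(m), 18L)
  expect_true(all(m$low_snr))
})

test_that("trace shorter than its protocol is a structural error", {
  tr <- simulate_recording(build_protocol(), config = quiet_config())
  short <- tr[tr$time < 5, ]
  attr(short, "meta") <- wave_meta(tr)
  attr(short, "stage") <- "filtered"
  class(short) <- class(tr)
  expect_error(detect_pulses(short), "shorter")
})

test_that("measure_amplitude is deterministic and flags rails", {
  pulse <- c(0, 0.2, 1.5, 0.7, -0.4, -0.1, 0)
  base <- rep(0.1, 20)
  out <- measure_amplitude(pulse, base)
  expect_equal(out$amplitude, 1.4)  # extremum minus median baseline
  expect_equal(out$baseline, 0.1)
  expect_false(out$clipped)
  # flat window has zero amplitude
  expect_equal(measure_amplitude(rep(0, 10), rep(0, 10))$amplitude, 0)
  # peak-to-peak convention
  expect_equal(measure_amplitude(pulse, base,
                                 convention = "peak_to_peak")$amplitude, 1.9)
  # two consecutive rail samples set the clipped flag
  railed <- c(0, 0.05, 0.05, 0.01)
  expect_true(measure_amplitude(railed, rep(0, 5), rail = 0.05)$clipped)
  expect_false(measure_amplitude(c(0, 0.05, 0.01), rep(0, 5),
                                 rail = 0.05)$clipped)
  expect_error(measure_amplitude(numeric(0), rep(0, 5)), "non-empty")
})

test_that("amplitude extraction ignores DC offsets and scales with the signal", {
  cfg <- quiet_config()
  tr <- simulate_recording(config = cfg)
  m0 <- detect_pulses(tr)
  # a constant baseline shift leaves baseline-referenced amplitudes exactly
  # unchanged
  tr_dc <- tr
  tr_dc$voltage <- tr$voltage + 1e-3
  attr(tr_dc, "meta") <- wave_meta(tr)
  attr(tr_dc, "stage") <- "filtered"
  m_dc <- detect_pulses(tr_dc)
  expect_equal(m_dc$amplitude, m0$amplitude)
  # scaling the device output below clip scales amplitudes proportionally
  tr_half <- simulate_recording(config = cfg, output_scale = 0.5)
  m_half <- detect_pulses(tr_half)
  expect_equal(m_half$amplitude / m0$amplitude, rep(0.5, 18), tolerance = 0.01)
})

test_that("curve assembly averages pulses per step and handles repeats", {
  tr <- simulate_recording(config = quiet_config())
  m <- detect_pulses(tr)
  cv <- assemble_curve(m, settings = knob_settings())
  expect_identical(nrow(cv), 9L)
  expect_true(all(cv$n_pulses == 2L))
  expect_true(attr(cv, "fittable"))
  expect_true(all(diff(cv$luminance) > 0))
  # fully flagged step gets merged from a repeat trace
  m_bad <- m
  m_bad$artifact[m_bad$step == 5] <- TRUE
  cv_gap <- assemble_curve(m_bad, settings = knob_settings())
  expect_identical(nrow(cv_gap), 8L)
  expect_identical(attr(cv_gap, "repeat_steps"), 5L)
  cv_fix <- assemble_curve(m_bad, settings = knob_settings(),
                           repeat_measurements = m)
  expect_identical(nrow(cv_fix), 9L)
  # empty input is an unfittable curve, not an error
  empty <- assemble_curve(m[0, ])
  expect_false(attr(empty, "fittable"))
  expect_true(fit_sigmoid(empty)$converged == FALSE)
})

test_that("sigmoid fit recovers generating parameters from analytic curves", {
  truth <- knob_to_params(20, 65)
  fit <- fit_sigmoid(make_curve(truth, settings = knob_settings(20, 65)))
  expect_true(fit$converged)
  expect_false(fit$degenerate)
  expect_lt(abs(fit$params$x_mid - truth$x_mid), 0.01)
  expect_lt(abs(fit$params$v_max - truth$v_max) / truth$v_max, 0.01)
  expect_lt(abs(fit$params$slope - truth$slope) / truth$slope, 0.05)
  expect_equal(fit$dynamic_range, 2.0, tolerance = 0.05)
})

test_that("simulate-then-fit recovers x_mid and v_max (noiseless chain)", {
  truth <- knob_to_params(20, 65)
  tr <- simulate_recording(config = quiet_config())
  fit <- fit_sigmoid(assemble_curve(detect_pulses(tr),
                                    settings = knob_settings(20, 65)))
  expect_true(fit$converged)
  expect_lt(abs(fit$params$x_mid - truth$x_mid), 0.05)
  # amplitudes are scaled by the recording chain, so v_max is checked in
  # shape space: the fitted dynamic range reflects the generating slope
  expect_equal(fit$dynamic_range, 2.0, tolerance = 0.3)
  expect_lt(fit$rmse / fit$params$v_max, 0.01)
})

test_that("degenerate and unfittable curves are reported honestly", {
  flat <- tibble::tibble(step = 1:9, luminance = 10^seq(-1, 3, 0.5),
                         amplitude = rep(0.005, 9), n_pulses = 1L)
  class(flat) <- c("crir_curve", class(flat))
  f <- fit_sigmoid(flat)
  expect_true(f$degenerate)
  expect_false(f$converged)
  expect_null(f$region_bounds)
  two <- make_curve(knob_to_params(20, 65), luminances = c(1, 10))
  expect_false(fit_sigmoid(two)$converged)
})

test_that("region classification follows the 10/90 bounds, closed interval", {
  fit <- fit_sigmoid(make_curve(knob_to_params(20, 65)))
  lo <- fit$region_bounds[["l_lo"]]
  hi <- fit$region_bounds[["l_hi"]]
  expect_equal(as.character(classify_region(lo * 0.5, fit)), "subthreshold")
  expect_equal(as.character(classify_region(sqrt(lo * hi), fit)), "slope")
  expect_equal(as.character(classify_region(hi * 2, fit)), "saturation")
  # bounds themselves belong to the slope region
  expect_equal(as.character(classify_region(c(lo, hi), fit)),
               c("slope", "slope"))
  expect_error(classify_region(-1, fit), "> 0")
  flat <- fit_sigmoid(make_curve(transfer_params(0.01, 0.0100001, 0, 1)))
  expect_error(classify_region(1, flat), "converged")
})

test_that("contrast resolvability requires both luminances on the slope", {
  fit <- fit_sigmoid(make_curve(knob_to_params(20, 65)))
  hi <- fit$region_bounds[["l_hi"]]
  mid <- fit$params$x_mid
  # both mid-slope, 0.5 log apart: resolvable with positive difference
  rc <- resolvable_contrast(fit, 10^(mid - 0.25), 10^(mid + 0.25))
  expect_true(rc$resolvable)
  expect_gt(rc$delta_amplitude, 0)
  # both in saturation: not resolvable, difference ~ 0
  rc_sat <- resolvable_contrast(fit, hi * 10, hi * 30)
  expect_false(rc_sat$resolvable)
  expect_lt(rc_sat$delta_amplitude, 0.02 * fit$params$v_max)
  expect_error(resolvable_contrast(fit, 5, 5), "differ")
})

test_that("fitted curve families preserve the generating parameter orderings", {
  # 12-setting grid, noiseless: fitted x_mid must order by v_gl and fitted
  # v_max by v_bias, exactly as generated
  grid <- expand.grid(v_gl = c(10, 35, 60), v_bias = c(30, 50, 65, 80))
  cfg <- quiet_config()
  fits <- purrr::map(seq_len(nrow(grid)), function(i) {
    s <- knob_settings(grid$v_gl[i], grid$v_bias[i])
    tr <- simulate_recording(settings = s, config = cfg)
    fit_sigmoid(assemble_curve(detect_pulses(tr), settings = s))
  })
  expect_true(all(purrr::map_lgl(fits, "converged")))
  est <- tibble::tibble(
    v_gl = grid$v_gl, v_bias = grid$v_bias,
    x_mid = purrr::map_dbl(fits, ~ .x$params$x_mid),
    v_max = purrr::map_dbl(fits, ~ .x$params$v_max)
  )
  truth <- knob_to_params(grid$v_gl, grid$v_bias)
  for (vb in unique(est$v_bias)) {
    sub <- est[est$v_bias == vb, ]
    tru <- truth[truth$v_bias == vb, ]
    expect_identical(order(sub$x_mid), order(tru$x_mid))
  }
  for (vg in unique(est$v_gl)) {
    sub <- est[est$v_gl == vg, ]
    tru <- truth[truth$v_gl == vg, ]
    expect_identical(order(sub$v_max), order(tru$v_max))
  }
})

test_that("tidy and glance summarize fits", {
  fit <- fit_sigmoid(make_curve(knob_to_params(20, 65),
                                settings = knob_settings(20, 65)))
  td <- tidy(fit)
  expect_identical(td$term, c("v_min", "v_max", "x_mid", "slope"))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$converged)
  expect_equal(gl$dynamic_range, 2, tolerance = 0.05)
  expect_identical(gl$n_points, 9L)
})
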