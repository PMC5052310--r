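# Independent oracles used across the suite.

# Brute-force dynamic range: scan a dense luminance grid for the crossings
# of v_min + frac * (v_max - v_min).
grid_dynamic_range <- function(params, lo_frac = 0.1, hi_frac = 0.9,
                               n = 200001, x_range = c(-8, 8)) {
  x <- seq(x_range[1], x_range[2], length.out = n)
  v <- transfer_voltage(10^x, params)
  lo_level <- params$v_min + lo_frac * (params$v_max - params$v_min)
  hi_level <- params$v_min + hi_frac * (params$v_max - params$v_min)
  x_lo <- x[which(v >= lo_level)[1]]
  x_hi <- x[which(v >= hi_level)[1]]
  list(l_lo = 10^x_lo, l_hi = 10^x_hi, span = x_hi - x_lo,
       step = diff(x[1:2]))
}

# Counting oracle for chip pulses inside a flash window.
count_pulses_oracle <- function(flash_duration, frequency, phase) {
  period <- 1 / frequency
  k <- 0L
  n <- 0L
  while (phase + k * period < flash_duration - 1e-12) {
    n <- n + 1L
    k <- k + 1L
  }
  n
}

# Analytic impulse response of the analog band-pass that the digital
# implementation discretizes (2nd-order Bessel HP x LP, prewarped
# cut-offs), via partial fractions: H(s) = k s^2 / prod(s - p_i),
# h(t) = sum_i r_i exp(p_i t) with r_i = k p_i^2 / prod_{j!=i}(p_i - p_j).
analog_bandpass_impulse <- function(f_low, f_high, fs, t) {
  pp <- polyroot(c(3, 3, 1))
  w3 <- sqrt((sqrt(45) - 3) / 2)
  p1 <- pp / w3
  wl <- 2 * fs * tan(pi * f_low / fs)
  wh <- 2 * fs * tan(pi * f_high / fs)
  poles <- c(wl / p1, p1 * wh)
  k <- Re(prod(-p1 * wh))
  h <- vapply(t, function(tt) {
    if (tt < 0) return(0)
    val <- 0i
    for (i in seq_along(poles)) {
      r <- k * poles[i]^2 / prod(poles[i] - poles[-i])
      val <- val + r * exp(poles[i] * tt)
    }
    Re(val)
  }, numeric(1))
  h
}

# Analytic curve -> fit helper: build a crir_curve directly from a
# transfer characteristic, bypassing the signal chain.
make_curve <- function(params, settings = NULL,
                       luminances = 10^seq(-1, 3, 0.5), noise = 0,
                       seed = 1) {
  a <- transfer_voltage(luminances, params)
  if (noise > 0) {
    a <- a + withr::with_seed(seed, stats::rnorm(length(a), 0, noise))
  }
  out <- tibble::tibble(step = seq_along(luminances), luminance = luminances,
                        amplitude = a, n_pulses = 1L)
  attr(out, "settings") <- settings
  attr(out, "fittable") <- length(luminances) >= 3
  class(out) <- c("crir_curve", class(out))
  out
}

make_fit <- function(v_gl, v_bias, v_min, v_max, x_mid, slope) {
  p <- transfer_params(v_min, v_max, x_mid, slope)
  fit_sigmoid(make_curve(p, settings = knob_settings(v_gl, v_bias)))
}

quiet_config <- function(...) recording_config(noise_rms = 0, ...)
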