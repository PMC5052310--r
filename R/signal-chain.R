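#' Chip configuration
#'
#' Constants of the microphotodiode array (MPDA): 1500 independent
#' photodiode-amplifier-electrode pixels on a 3 mm square, emitting one
#' rectangular anodic voltage pulse per frame. Under full-field stimulation
#' all pixels see the same luminance, so the array is modeled as a single
#' lumped source.
#'
#' @param n_pixels Number of pixels.
#' @param pulse_duration Pulse width, seconds; allowed 0.1--2 ms and must be
#'   shorter than one frame period.
#' @param working_frequency Frame rate, Hz; allowed 1--20.
#' @param electrode_edge Electrode edge length, meters (metadata).
#' @param chip_edge Chip edge length, meters (metadata).
#' @return An object of class `chip_config`.
#' @export
chip_config <- function(n_pixels = 1500, pulse_duration = 1e-3,
                        working_frequency = 5,
                        electrode_edge = 50e-6, chip_edge = 3e-3) {
  if (!(pulse_duration >= 1e-4 && pulse_duration <= 2e-3)) {
    stop("`pulse_duration` must lie in [0.1, 2] ms", call. = FALSE)
  }
  if (!(working_frequency >= 1 && working_frequency <= 20)) {
    stop("`working_frequency` must lie in [1, 20] Hz", call. = FALSE)
  }
  if (!(pulse_duration < 1 / working_frequency)) {
    stop("`pulse_duration` must be shorter than one frame period", call. = FALSE)
  }
  structure(list(n_pixels = n_pixels, pulse_duration = pulse_duration,
                 working_frequency = working_frequency,
                 electrode_edge = electrode_edge, chip_edge = chip_edge),
            class = "chip_config")
}

#' Recording configuration
#'
#' Parameters of the electroretinographic acquisition chain: a DC amplifier
#' with fixed gain 10 and +/- 0.5 V input range, a 16-bit ADC (with a
#' 12-bit DC offset register, modeled as an additive baseline, default 0),
#' 5 kHz sampling, and a built-in digital band-pass (second-order cascaded
#' Bessel filter, -3 dB at 0.312 and 300 Hz).
#'
#' @param sampling_rate Samples per second, Hz.
#' @param amp_gain Amplifier gain (dimensionless).
#' @param input_range Half-range of the amplifier/ADC input, volts (i.e.
#'   +/- `input_range` after the gain stage).
#' @param adc_bits ADC resolution, bits.
#' @param dc_offset_bits Resolution of the DC offset register, bits; must
#'   not exceed `adc_bits`.
#' @param dc_offset DC offset applied at the amplifier output, volts
#'   (quantized to `dc_offset_bits` over the input range).
#' @param f_low,f_high Band-pass -3 dB cut-off frequencies, Hz.
#' @param filter_order Order of each cascaded Bessel section.
#' @param noise_rms RMS of the Gaussian noise referred to the amplifier
#'   input, volts; 0 disables noise.
#' @param seed Integer seed governing all stochastic elements (noise).
#' @return An object of class `recording_config`.
#' @export
recording_config <- function(sampling_rate = 5000, amp_gain = 10,
                             input_range = 0.5, adc_bits = 16,
                             dc_offset_bits = 12, dc_offset = 0,
                             f_low = 0.312, f_high = 300,
                             filter_order = 2, noise_rms = 20e-6,
                             seed = 1L) {
  if (!(f_low > 0 && f_low < f_high)) {
    stop("need 0 < f_low < f_high", call. = FALSE)
  }
  if (!(f_high < sampling_rate / 2)) {
    stop("`f_high` must be below the Nyquist frequency", call. = FALSE)
  }
  if (dc_offset_bits > adc_bits) {
    stop("`dc_offset_bits` must not exceed `adc_bits`", call. = FALSE)
  }
  structure(list(sampling_rate = sampling_rate, amp_gain = amp_gain,
                 input_range = input_range, adc_bits = adc_bits,
                 dc_offset_bits = dc_offset_bits, dc_offset = dc_offset,
                 f_low = f_low, f_high = f_high, filter_order = filter_order,
                 noise_rms = noise_rms, seed = as.integer(seed)),
            class = "recording_config")
}

new_wave <- function(time, value, col, stage, meta) {
  out <- tibble::tibble(time = time, "{col}" := value)
  attr(out, "meta") <- meta
  attr(out, "stage") <- stage
  class(out) <- c("crir_wave", class(out))
  out
}

#' Waveform metadata
#'
#' @param x A waveform/trace tibble produced by the simulation chain.
#' @return The metadata list attached by the simulator (protocol, settings,
#'   configs, pulse table, artifact windows, provenance).
#' @export
wave_meta <- function(x) attr(x, "meta")

#' Synthesize the chip output waveform
#'
#' Places a rectangular anodic (nonnegative) voltage pulse of width
#' `chip$pulse_duration` at each expected chip frame inside each flash,
#' with amplitude given by the transfer characteristic at that flash's
#' luminance; the waveform is zero elsewhere (the dark output `v_min`
#' only produces pulses during flashes in this model, the dark-frame pulses
#' being indistinguishable from baseline at the recording scale except
#' through `v_min` itself, which scales the lowest flash steps).
#'
#' @param protocol A [build_protocol()] object.
#' @param settings A [knob_settings()] object.
#' @param chip A [chip_config()] object.
#' @param calibration A [crir_calibration()] object.
#' @param sampling_rate Simulation sampling rate, Hz.
#' @param phase Chip frame phase relative to flash onset, seconds.
#' @return A `crir_wave` tibble with columns `time`, `v_chip` (volts) and a
#'   metadata attribute carrying the pulse table (step, luminance, onset,
#'   amplitude) and all configuration objects.
#' @export
synthesize_chip_waveform <- function(protocol, settings = knob_settings(),
                                     chip = chip_config(),
                                     calibration = crir_calibration(),
                                     sampling_rate = 5000, phase = 0) {
  stopifnot(inherits(protocol, "stim_protocol"),
            inherits(settings, "knob_settings"))
  params <- knob_to_params(settings, calibration = calibration)
  pulses <- expected_pulse_times(protocol, chip, phase)
  pulses$amplitude <- vapply(pulses$luminance,
                             function(L) transfer_voltage(L, params),
                             numeric(1))
  dt <- 1 / sampling_rate
  n <- ceiling(protocol$duration * sampling_rate)
  time <- (seq_len(n) - 1) * dt
  v <- numeric(n)
  width <- max(1L, round(chip$pulse_duration * sampling_rate))
  for (i in seq_len(nrow(pulses))) {
    i0 <- round(pulses$time[i] * sampling_rate) + 1L
    idx <- i0:min(n, i0 + width - 1L)
    v[idx] <- pulses$amplitude[i]
  }
  meta <- list(protocol = protocol, settings = settings, chip = chip,
               calibration = calibration, params = params,
               sampling_rate = sampling_rate, phase = phase, pulses = pulses)
  new_wave(time, v, "v_chip", "chip", meta)
}

#' Couple the chip waveform to the cornea
#'
#' The electrode-tissue interface is capacitive, so each rectangular chip
#' pulse appears at the cornea as a charge-balanced biphasic deflection: a
#' positive lobe during the pulse followed by an opposite-sign overshoot
#' after pulse offset and an exponential return to baseline. The coupling
#' is modeled as a single-pole high-pass with time constant `tau` and a
#' scalar attenuation; the peak corneal amplitude equals
#' `attenuation * pulse amplitude`. The model-internal interface current
#' `i_chip` and per-pulse injected charge `q_chip` (integral of the
#' positive current lobe) are reported alongside.
#'
#' @param chip_wave A `crir_wave` from [synthesize_chip_waveform()].
#' @param tau Coupling time constant, seconds (default from the waveform's
#'   calibration).
#' @param attenuation Chip-to-cornea amplitude attenuation (default from
#'   the calibration).
#' @param r_access Access resistance converting the corneal voltage into
#'   the model-internal interface current, ohms.
#' @return A `crir_wave` tibble with `time`, `v_cornea` (volts) and
#'   `i_chip` (amps); per-pulse `q_chip` (coulombs) is appended to the
#'   pulse table in the metadata.
#' @export
couple_to_cornea <- function(chip_wave, tau = NULL, attenuation = NULL,
                             r_access = 1e4) {
  stopifnot(inherits(chip_wave, "crir_wave"),
            attr(chip_wave, "stage") == "chip")
  meta <- wave_meta(chip_wave)
  cal <- meta$calibration
  if (is.null(tau)) tau <- cal$coupling_tau
  if (is.null(attenuation)) attenuation <- cal$coupling_atten
  fs <- meta$sampling_rate
  a <- exp(-1 / (fs * tau))
  x <- chip_wave$v_chip
  # y[n] = a y[n-1] + atten (x[n] - x[n-1]): discrete single-pole high-pass
  dx <- c(x[1], diff(x))
  y <- attenuation * as.numeric(stats::filter(dx, a, method = "recursive"))
  i_chip <- y / (attenuation * r_access)
  dt <- 1 / fs
  pulses <- meta$pulses
  period <- 1 / meta$chip$working_frequency
  pulses$q_chip <- vapply(seq_len(nrow(pulses)), function(k) {
    idx <- which(chip_wave$time >= pulses$time[k] &
                   chip_wave$time < pulses$time[k] + period)
    sum(pmax(i_chip[idx], 0)) * dt
  }, numeric(1))
  meta$pulses <- pulses
  meta$coupling <- list(tau = tau, attenuation = attenuation,
                        r_access = r_access)
  out <- new_wave(chip_wave$time, y, "v_cornea", "cornea", meta)
  out$i_chip <- i_chip
  out
}

#' Amplify, clip and digitize a corneal waveform
#'
#' Applies the amplifier gain, hard-clips at the +/- `input_range` rails,
#' adds the (quantized) DC offset, quantizes uniformly to `adc_bits` levels
#' over the input range, and returns values referred back to the amplifier
#' input (divided by the gain). Samples at a rail are flagged.
#'
#' @param cornea A `crir_wave` from [couple_to_cornea()], or any wave whose
#'   voltage column is referred to the amplifier input.
#' @param config A [recording_config()] object.
#' @return A `crir_wave` tibble with `time`, `voltage` (volts, referred to
#'   input) and a logical `clipped` column; metadata gains a `clipped_any`
#'   flag and the config.
#' @export
amplify_and_digitize <- function(cornea, config = recording_config()) {
  stopifnot(inherits(cornea, "crir_wave"), inherits(config, "recording_config"))
  meta <- wave_meta(cornea)
  vcol <- setdiff(names(cornea), c("time", "i_chip"))[1]
  v_amp <- cornea[[vcol]] * config$amp_gain
  offset_lsb <- 2 * config$input_range / 2^config$dc_offset_bits
  dc <- round(config$dc_offset / offset_lsb) * offset_lsb
  v_amp <- v_amp + dc
  rail <- config$input_range
  clipped <- v_amp >= rail | v_amp <= -rail
  v_amp <- pmin(pmax(v_amp, -rail), rail)
  lsb <- 2 * rail / 2^config$adc_bits
  code <- round((v_amp + rail) / lsb)
  code <- pmin(code, 2^config$adc_bits - 1)
  v_q <- (code * lsb - rail) / config$amp_gain
  meta$config <- config
  meta$clipped_any <- any(clipped)
  out <- new_wave(cornea$time, v_q, "voltage", "digitized", meta)
  out$clipped <- clipped
  out
}

#' Design the digital Bessel band-pass filter
#'
#' Realizes the acquisition system's band-pass as a cascade of a
#' second-order Bessel high-pass and a second-order Bessel low-pass. Each
#' section starts from the closed-form analog Bessel prototype (poles of
#' `s^2 + 3s + 3`, rescaled so its -3 dB point sits at 1 rad/s), is scaled
#' to the prewarped cut-off, and is discretized with the bilinear transform
#' ([signal::bilinear()]). Prewarping puts the realized -3 dB points at the
#' requested frequencies.
#'
#' @param f_low,f_high Cut-off frequencies, Hz.
#' @param sampling_rate Sampling rate, Hz.
#' @return A list of class `crir_filter` with `hp` and `lp` (each a
#'   [signal::Arma()] section, applied in cascade), plus the design
#'   frequencies.
#' @export
design_bessel_bandpass <- function(f_low = 0.312, f_high = 300,
                                   sampling_rate = 5000) {
  if (!(f_low > 0 && f_low < f_high && f_high < sampling_rate / 2)) {
    stop("cut-offs must satisfy 0 < f_low < f_high < Nyquist", call. = FALSE)
  }
  # delay-normalized 2nd-order Bessel poles; -3 dB of that prototype
  p <- polyroot(c(3, 3, 1))
  w3 <- sqrt((sqrt(45) - 3) / 2)
  p1 <- p / w3                      # -3 dB now at 1 rad/s
  section <- function(fc, type) {
    wc <- 2 * sampling_rate * tan(pi * fc / sampling_rate)  # prewarp
    if (type == "low") {
      Sp <- p1 * wc; Sz <- numeric(0); Sg <- Re(prod(-Sp))
    } else {
      Sp <- wc / p1; Sz <- c(0, 0); Sg <- 1
    }
    signal::as.Arma(signal::bilinear(Sz, Sp, Sg, T = 1 / sampling_rate))
  }
  structure(list(hp = section(f_low, "high"), lp = section(f_high, "low"),
                 f_low = f_low, f_high = f_high,
                 sampling_rate = sampling_rate),
            class = "crir_filter")
}

#' Magnitude response of the designed band-pass
#'
#' @param filt A `crir_filter` from [design_bessel_bandpass()].
#' @param f Frequencies at which to evaluate, Hz.
#' @return Numeric vector of magnitude gains.
#' @export
filter_gain <- function(filt, f) {
  w <- 2 * pi * f / filt$sampling_rate
  h <- function(sec, w1) {
    zi <- exp(-1i * w1 * (seq_along(sec$b) - 1))
    za <- exp(-1i * w1 * (seq_along(sec$a) - 1))
    sum(sec$b * zi) / sum(sec$a * za)
  }
  vapply(w, function(w1) abs(h(filt$hp, w1) * h(filt$lp, w1)), numeric(1))
}

#' Measured -3 dB points of the realized filter
#'
#' Locates the frequencies where the realized digital filter's gain falls
#' 3 dB below its passband maximum, by root-finding on the magnitude
#' response.
#'
#' @param filt A `crir_filter` object.
#' @return Named numeric vector `c(low = , high = )`, Hz.
#' @export
measure_cutoffs <- function(filt) {
  f_ref <- exp(seq(log(filt$f_low), log(filt$f_high), length.out = 200))
  g_pass <- max(filter_gain(filt, f_ref))
  target <- g_pass / sqrt(2)
  gfun <- function(f) filter_gain(filt, f) - target
  geo <- sqrt(filt$f_low * filt$f_high)
  lo <- stats::uniroot(gfun, c(filt$f_low / 100, geo), tol = 1e-10)$root
  hi <- stats::uniroot(gfun, c(geo, filt$sampling_rate / 2 * 0.999),
                       tol = 1e-7)$root
  c(low = lo, high = hi)
}

#' Apply the Bessel band-pass to a trace
#'
#' Filters causally (single pass, high-pass then low-pass section), as the
#' acquisition system filters online; the output therefore shows the
#' characteristic signal delay and pulse broadening of the convolution
#' with the filter's impulse response.
#'
#' @param trace A `crir_wave` (any stage) or a numeric vector of samples.
#' @param config A [recording_config()] object (ignored when `filt` given).
#' @param filt Optionally a pre-designed `crir_filter`.
#' @return Same shape as the input, filtered; for waves the stage becomes
#'   `"filtered"` and the voltage column is named `voltage`.
#' @export
bessel_bandpass <- function(trace, config = recording_config(), filt = NULL) {
  if (is.null(filt)) {
    filt <- design_bessel_bandpass(config$f_low, config$f_high,
                                   config$sampling_rate)
  }
  run <- function(x) {
    x <- as.numeric(signal::filter(filt$hp$b, filt$hp$a, x))
    as.numeric(signal::filter(filt$lp$b, filt$lp$a, x))
  }
  if (is.numeric(trace)) return(run(trace))
  stopifnot(inherits(trace, "crir_wave"))
  meta <- wave_meta(trace)
  vcol <- setdiff(names(trace), c("time", "i_chip", "clipped"))[1]
  meta$filter <- filt
  out <- new_wave(trace$time, run(trace[[vcol]]), "voltage", "filtered", meta)
  if ("clipped" %in% names(trace)) out$clipped <- trace$clipped
  out
}

#' Add seeded noise and labeled artifacts to a trace
#'
#' Adds Gaussian noise of `config$noise_rms` (volts, referred to the
#' amplifier input) and optionally injects artifacts with ground-truth
#' labels recorded in the metadata: `"blink"` (a smooth low-frequency
#' transient) or `"dropout"` (a segment forced to zero). With
#' `noise_rms = 0` and no artifacts the samples are returned unchanged.
#' All randomness derives from `config$seed` (plus `seed_offset`), so the
#' same configuration reproduces the same trace bit for bit.
#'
#' @param trace A `crir_wave` at any stage.
#' @param config A [recording_config()] object.
#' @param artifacts Optional list of artifact descriptors, each a list with
#'   `type` ("blink" or "dropout"), `time` (s), `duration` (s) and for
#'   blinks an `amplitude` (volts, default 2 mV).
#' @param seed_offset Integer added to `config$seed`, letting one config
#'   drive several independent traces.
#' @return The trace with noise/artifacts applied; metadata gains
#'   `artifact_windows` (a tibble with `type`, `start`, `end`) and
#'   `noise_seed`.
#' @export
add_noise_and_artifacts <- function(trace, config = recording_config(),
                                    artifacts = NULL, seed_offset = 0L) {
  stopifnot(inherits(trace, "crir_wave"))
  meta <- wave_meta(trace)
  vcol <- setdiff(names(trace), c("time", "i_chip", "clipped"))[1]
  v <- trace[[vcol]]
  seed <- (config$seed + as.integer(seed_offset)) %% .Machine$integer.max
  if (config$noise_rms > 0) {
    v <- v + withr::with_seed(seed, stats::rnorm(length(v), 0, config$noise_rms))
  }
  windows <- tibble::tibble(type = character(), start = numeric(),
                            end = numeric())
  for (a in artifacts) {
    t0 <- a$time
    t1 <- a$time + a$duration
    idx <- which(trace$time >= t0 & trace$time < t1)
    if (length(idx) == 0) next
    if (a$type == "blink") {
      amp <- if (is.null(a$amplitude)) 2e-3 else a$amplitude
      tt <- trace$time[idx]
      v[idx] <- v[idx] + amp * exp(-0.5 * ((tt - (t0 + t1) / 2) /
                                             (a$duration / 6))^2)
    } else if (a$type == "dropout") {
      v[idx] <- 0
    } else {
      stop(sprintf("unknown artifact type '%s'", a$type), call. = FALSE)
    }
    windows <- dplyr::bind_rows(windows,
                                tibble::tibble(type = a$type, start = t0, end = t1))
  }
  meta$artifact_windows <- windows
  meta$noise_seed <- if (config$noise_rms > 0) seed else NA_integer_
  out <- new_wave(trace$time, v, vcol, attr(trace, "stage"), meta)
  if ("clipped" %in% names(trace)) out$clipped <- trace$clipped
  out
}

#' Simulate a full recording
#'
#' Composes the whole acquisition chain: chip pulse train, capacitive
#' coupling to the cornea, additive input-referred noise and labeled
#' artifacts, amplification/clipping/quantization, and the causal digital
#' Bessel band-pass. The result is a recorded trace as the ERG system
#' would store it, with full provenance in its metadata.
#'
#' @inheritParams synthesize_chip_waveform
#' @param config A [recording_config()] object.
#' @param artifacts Optional artifact list, see [add_noise_and_artifacts()].
#' @param seed_offset Integer offset applied to `config$seed`.
#' @param output_scale Extra multiplicative factor on the chip output
#'   (1 = nominal); 0 emulates a dead device (e.g. a broken cable).
#' @return A `crir_wave` of stage `"filtered"` with columns `time`,
#'   `voltage` (volts referred to the amplifier input) and `clipped`.
#' @examples
#' trace <- simulate_recording(build_protocol(), knob_settings(20, 65))
#' @export
simulate_recording <- function(protocol = build_protocol(),
                               settings = knob_settings(),
                               chip = chip_config(),
                               config = recording_config(),
                               calibration = crir_calibration(),
                               phase = 0, artifacts = NULL,
                               seed_offset = 0L, output_scale = 1) {
  chip_wave <- synthesize_chip_waveform(protocol, settings, chip, calibration,
                                        sampling_rate = config$sampling_rate,
                                        phase = phase)
  if (output_scale != 1) {
    chip_wave$v_chip <- chip_wave$v_chip * output_scale
    meta <- wave_meta(chip_wave)
    meta$pulses$amplitude <- meta$pulses$amplitude * output_scale
    meta$output_scale <- output_scale
    attr(chip_wave, "meta") <- meta
  }
  cornea <- couple_to_cornea(chip_wave)
  noisy <- add_noise_and_artifacts(cornea, config, artifacts, seed_offset)
  digitized <- amplify_and_digitize(noisy, config)
  bessel_bandpass(digitized, config)
}
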