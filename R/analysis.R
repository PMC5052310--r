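#' Detect stimulus-locked implant pulses in a recorded trace
#'
#' For every chip pulse expected from the stimulus protocol and chip frame
#' rate, opens a search window around the expected onset, measures the
#' response amplitude against a pre-pulse baseline, and attaches quality
#' flags. Pulses whose amplitude stays below the detection threshold are
#' reported with a `low_snr` flag rather than dropped, so subthreshold
#' steps still contribute (small) amplitudes to the curve.
#'
#' Flags:
#' * `clipped` — the digitizer railed for at least two consecutive samples
#'   inside the window (read from simulation metadata when available,
#'   otherwise inferred from samples at the rails);
#' * `artifact` — the window overlaps a labeled artifact window, or the
#'   baseline spread is grossly inconsistent with the configured noise;
#' * `low_snr` — amplitude below `snr_k` times the noise RMS.
#'
#' @param trace A recorded trace: a `crir_wave` from [simulate_recording()]
#'   or [read_trace()], with protocol/config metadata.
#' @param protocol,chip,config Override the metadata copies if supplied.
#' @param phase Chip frame phase, seconds (defaults to the metadata value).
#' @param search_halfwidth Half-width of the search window, seconds.
#' @param baseline_width Width of the pre-pulse baseline window, seconds.
#' @param snr_k Detection threshold in multiples of the noise RMS.
#' @param convention `"baseline_to_peak"` (default: signed extremum of the
#'   dominant first lobe minus the median pre-pulse baseline) or
#'   `"peak_to_peak"`.
#' @return A tibble with one row per expected pulse: `step`, `luminance`,
#'   `pulse_index`, `expected_time`, `pulse_time`, `baseline`, `amplitude`
#'   (volts) and logical `clipped`, `artifact`, `low_snr`.
#' @export
detect_pulses <- function(trace, protocol = NULL, chip = NULL, config = NULL,
                          phase = NULL, search_halfwidth = 0.020,
                          baseline_width = 0.050, snr_k = 5,
                          convention = c("baseline_to_peak", "peak_to_peak")) {
  convention <- match.arg(convention)
  stopifnot(inherits(trace, "crir_wave"))
  meta <- wave_meta(trace)
  protocol <- protocol %||% meta$protocol
  chip <- chip %||% meta$chip
  config <- config %||% meta$config
  phase <- phase %||% meta$phase %||% 0
  if (is.null(protocol) || is.null(chip) || is.null(config)) {
    stop("trace metadata lacks protocol/chip/config; pass them explicitly",
         call. = FALSE)
  }
  if (protocol$duration > max(trace$time) + 1 / config$sampling_rate) {
    stop("trace is shorter than the protocol it claims to realize",
         call. = FALSE)
  }
  expected <- expected_pulse_times(protocol, chip, phase)
  fs <- config$sampling_rate
  noise_ref <- max(config$noise_rms,
                   2 * config$input_range / 2^config$adc_bits / config$amp_gain)
  art <- meta$artifact_windows
  v <- trace$voltage
  clipped_samples <- if ("clipped" %in% names(trace)) trace$clipped else {
    rail <- config$input_range / config$amp_gain
    lsb_in <- 2 * config$input_range / 2^config$adc_bits / config$amp_gain
    abs(v) >= rail - lsb_in
  }

  purrr::map_dfr(seq_len(nrow(expected)), function(i) {
    t0 <- expected$time[i]
    win <- which(trace$time >= t0 - search_halfwidth &
                   trace$time <= t0 + search_halfwidth)
    base_idx <- which(trace$time >= t0 - search_halfwidth - baseline_width &
                        trace$time < t0 - search_halfwidth)
    baseline <- if (length(base_idx)) stats::median(v[base_idx]) else 0
    dev <- v[win] - baseline
    if (convention == "baseline_to_peak") {
      k <- which.max(abs(dev))
      amplitude <- dev[k]
      pulse_time <- trace$time[win[k]]
    } else {
      amplitude <- max(dev) - min(dev)
      pulse_time <- trace$time[win[which.max(dev)]]
    }
    cl <- clipped_samples[win]
    clipped <- any(cl & dplyr::lag(cl, default = FALSE))
    overlaps_label <- !is.null(art) && nrow(art) > 0 &&
      any(art$start < t0 + search_halfwidth & art$end > t0 - search_halfwidth)
    baseline_spread <- if (length(base_idx))
      stats::mad(v[base_idx], constant = 1.4826) else 0
    artifact <- overlaps_label || baseline_spread > 10 * noise_ref
    tibble::tibble(
      step = expected$step[i], luminance = expected$luminance[i],
      pulse_index = expected$pulse_index[i], expected_time = t0,
      pulse_time = pulse_time, baseline = baseline, amplitude = amplitude,
      clipped = clipped, artifact = artifact,
      low_snr = abs(amplitude) < snr_k * noise_ref
    )
  })
}

#' Measure a pulse amplitude in an extracted window
#'
#' Formalizes the manual read-off of a response amplitude: the signed
#' extremum of the window relative to the median of the pre-pulse baseline
#' window (or peak-to-peak). Deterministic; flags rail clipping when two or
#' more consecutive samples sit at `rail`.
#'
#' @param window Numeric samples covering the response.
#' @param baseline_window Numeric samples immediately preceding the window.
#' @param rail Optional rail voltage (volts, referred to input) for clip
#'   detection.
#' @param convention See [detect_pulses()].
#' @return A one-row tibble with `amplitude`, `baseline`, `clipped`.
#' @export
measure_amplitude <- function(window, baseline_window, rail = NULL,
                              convention = c("baseline_to_peak",
                                             "peak_to_peak")) {
  convention <- match.arg(convention)
  if (length(window) == 0 || length(baseline_window) == 0) {
    stop("`window` and `baseline_window` must be non-empty", call. = FALSE)
  }
  baseline <- stats::median(baseline_window)
  dev <- window - baseline
  amplitude <- if (convention == "baseline_to_peak") {
    dev[which.max(abs(dev))]
  } else {
    max(dev) - min(dev)
  }
  clipped <- FALSE
  if (!is.null(rail)) {
    at_rail <- abs(window) >= rail * (1 - 1e-9)
    clipped <- any(at_rail & c(FALSE, at_rail[-length(at_rail)]))
  }
  tibble::tibble(amplitude = amplitude, baseline = baseline, clipped = clipped)
}

#' Assemble a response curve from pulse measurements
#'
#' Groups pulse measurements by luminance step, excludes artifact- or
#' clip-flagged pulses, averages the remaining amplitudes per step, and
#' returns the (luminance, amplitude) curve for one knob setting. A step
#' whose pulses are all flagged is marked for repetition — mirroring the
#' clinical rule that an artifacted luminance step is re-recorded — and is
#' filled in from `repeat_measurements` when supplied. `low_snr` pulses are
#' retained: a small amplitude at a dim flash is a real subthreshold
#' response, not a defect.
#'
#' @param measurements A tibble from [detect_pulses()].
#' @param protocol The protocol (defaults cannot be inferred; required
#'   only for bookkeeping when `measurements` lacks all steps).
#' @param settings The [knob_settings()] the trace was recorded at.
#' @param repeat_measurements Optional second [detect_pulses()] tibble from
#'   a repeat recording, used to fill steps whose pulses were all flagged.
#' @param min_points Minimum usable steps for the curve to be fittable.
#' @return A tibble of class `crir_curve` with `step`, `luminance`,
#'   `amplitude` (volts), `n_pulses`; attributes `settings`, `fittable`,
#'   `repeat_steps` (steps that needed a repeat).
#' @export
assemble_curve <- function(measurements, protocol = NULL, settings = NULL,
                           repeat_measurements = NULL, min_points = 3) {
  if (is.null(measurements) || nrow(measurements) == 0) {
    out <- tibble::tibble(step = integer(), luminance = numeric(),
                          amplitude = numeric(), n_pulses = integer())
    attr(out, "settings") <- settings
    attr(out, "fittable") <- FALSE
    attr(out, "repeat_steps") <- integer()
    class(out) <- c("crir_curve", class(out))
    return(out)
  }
  usable <- dplyr::filter(measurements, !.data$artifact, !.data$clipped)
  flagged_steps <- setdiff(unique(measurements$step), unique(usable$step))
  if (!is.null(repeat_measurements) && length(flagged_steps) > 0) {
    fill <- dplyr::filter(repeat_measurements, .data$step %in% flagged_steps,
                          !.data$artifact, !.data$clipped)
    usable <- dplyr::bind_rows(usable, fill)
  }
  pts <- usable |>
    dplyr::group_by(.data$step, .data$luminance) |>
    dplyr::summarise(amplitude = mean(.data$amplitude),
                     n_pulses = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$luminance)
  attr(pts, "settings") <- settings
  attr(pts, "fittable") <- nrow(pts) >= min_points
  attr(pts, "repeat_steps") <- flagged_steps
  class(pts) <- c("crir_curve", class(pts))
  pts
}

sigmoid10 <- function(x, v_min, dv, x_mid, slope) {
  v_min + dv / (1 + 10^(-slope * (x - x_mid)))
}

#' Fit the four-parameter logistic to a response curve
#'
#' Least-squares fit of
#' `A(L) = v_min + (v_max - v_min) / (1 + 10^(-slope (log10 L - x_mid)))`
#' to a `crir_curve`, recovering the in vivo transfer characteristic.
#' Initialization takes `v_min`/`v_max` from the amplitude extremes,
#' `x_mid` from the interpolated half-range crossing and the slope from the
#' endpoint secant; a fixed grid of multiplicative jitters provides
#' additional deterministic restarts, and the lowest-RSS converged fit
#' wins. Non-convergence and degenerate (flat) inputs are reported through
#' flags, never as errors.
#'
#' @param curve A `crir_curve` from [assemble_curve()], or any data frame
#'   with `luminance` and `amplitude` columns.
#' @param lo_frac,hi_frac Output fractions defining the slope region
#'   bounds (defaults 10%/90%).
#' @param degenerate_tol Minimal amplitude swing (volts) below which the
#'   curve is declared degenerate and not fitted.
#' @param n_starts Number of restarts (first is the data-driven start).
#' @return An object of class `crir_fit`: a list with `params` (a
#'   `transfer_params` row in the amplitude domain), `region_bounds`
#'   (`l_lo`, `l_hi` in cd/m2), `dynamic_range` (log10 units), `rmse`
#'   (volts), `converged`, `degenerate`, the input `curve` and `settings`.
#' @examples
#' curve <- assemble_curve(detect_pulses(simulate_recording()),
#'                         settings = knob_settings())
#' fit <- fit_sigmoid(curve)
#' glance(fit)
#' @export
fit_sigmoid <- function(curve, lo_frac = 0.1, hi_frac = 0.9,
                        degenerate_tol = 2e-6, n_starts = 5) {
  settings <- attr(curve, "settings")
  fittable <- attr(curve, "fittable") %||% (nrow(curve) >= 3)
  new_fit <- function(params = NULL, rmse = NA_real_, converged = FALSE,
                      degenerate = FALSE, note = NULL) {
    rb <- dr <- NULL
    if (converged && !degenerate) {
      drt <- dynamic_range(params, lo_frac, hi_frac)
      if (drt$degenerate) {
        degenerate <- TRUE
      } else {
        rb <- c(l_lo = drt$l_lo, l_hi = drt$l_hi)
        dr <- drt$span_log10
      }
    }
    structure(list(params = params, region_bounds = rb, dynamic_range = dr,
                   rmse = rmse, converged = converged, degenerate = degenerate,
                   lo_frac = lo_frac, hi_frac = hi_frac,
                   curve = curve, settings = settings, note = note),
              class = "crir_fit")
  }
  if (!fittable || nrow(curve) < 3) {
    return(new_fit(note = "fewer than 3 usable points"))
  }
  x <- log10(curve$luminance)
  a <- curve$amplitude
  swing <- diff(range(a))
  if (!is.finite(swing) || swing < degenerate_tol) {
    return(new_fit(degenerate = TRUE, note = "amplitude swing below tolerance"))
  }

  v_min0 <- min(a)
  dv0 <- swing
  half <- v_min0 + dv0 / 2
  above <- which(a >= half)
  x_mid0 <- if (length(above)) {
    j <- min(above)
    if (j == 1) x[1] else {
      # linear interpolation of the half-range crossing
      x[j - 1] + (half - a[j - 1]) / (a[j] - a[j - 1]) * (x[j] - x[j - 1])
    }
  } else stats::median(x)
  # endpoint secant in fraction-of-swing per log10 unit; the base-10
  # logistic's maximal derivative is ~0.576 * slope, so scale up
  sec <- (a[length(a)] - a[1]) / (dv0 * (x[length(x)] - x[1]))
  slope0 <- min(max(sec * 2, 0.2), 10)

  jitter_grid <- list(c(1, 1), c(0.5, 1), c(2, 1), c(1, 0.7), c(1, 1.4),
                      c(0.5, 0.7), c(2, 1.4))
  starts <- lapply(jitter_grid[seq_len(min(n_starts + 2, length(jitter_grid)))],
                   function(j) {
                     list(v_min = v_min0, dv = dv0,
                          x_mid = x_mid0 + log10(j[2]),
                          slope = slope0 * j[1])
                   })

  dat <- data.frame(x = x, a = a)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        a ~ sigmoid10(x, v_min, dv, x_mid, slope),
        data = dat, start = st,
        lower = c(v_min = -Inf, dv = 0, x_mid = min(x) - 5, slope = 1e-3),
        upper = c(v_min = Inf, dv = Inf, x_mid = max(x) + 5, slope = 50),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(new_fit(note = "no start converged"))
  cf <- stats::coef(best$fit)
  if (cf[["dv"]] < degenerate_tol) {
    return(new_fit(degenerate = TRUE, note = "fitted swing ~ 0"))
  }
  params <- transfer_params(v_min = max(cf[["v_min"]], 0),
                            v_max = max(cf[["v_min"]], 0) + cf[["dv"]],
                            x_mid = cf[["x_mid"]], slope = cf[["slope"]])
  if (!is.null(settings)) {
    params$v_gl <- settings$v_gl
    params$v_bias <- settings$v_bias
  }
  new_fit(params = params, rmse = sqrt(best$rss / nrow(curve)),
          converged = TRUE)
}

#' Predict amplitudes from a fitted curve
#'
#' @param object A `crir_fit`.
#' @param luminance Luminances (cd/m2) at which to evaluate; defaults to
#'   the fitted curve's own luminances.
#' @param ... Unused.
#' @return Numeric vector of predicted amplitudes (volts).
#' @export
predict.crir_fit <- function(object, luminance = NULL, ...) {
  stopifnot(object$converged, !object$degenerate)
  if (is.null(luminance)) luminance <- object$curve$luminance
  transfer_voltage(luminance, object$params)
}

#' @export
print.crir_fit <- function(x, ...) {
  cat("<crir_fit>")
  if (!is.null(x$settings)) cat(" settings", format(x$settings))
  cat("\n")
  if (x$degenerate) {
    cat("  degenerate (flat) curve\n")
  } else if (!x$converged) {
    cat("  did not converge:", x$note %||% "", "\n")
  } else {
    p <- x$params
    cat(sprintf("  v_min %.4g V, v_max %.4g V, x_mid %.3f log10 cd/m2, slope %.3f\n",
                p$v_min, p$v_max, p$x_mid, p$slope))
    cat(sprintf("  slope region %.3g .. %.3g cd/m2 (%.2f log10 units), rmse %.3g V\n",
                x$region_bounds[["l_lo"]], x$region_bounds[["l_hi"]],
                x$dynamic_range, x$rmse))
  }
  invisible(x)
}

#' Classify luminances into transfer-curve regions
#'
#' A luminance is `subthreshold` below the fitted 10% crossing (output too
#' low for perception), `saturation` above the 90% crossing (ceiling, no
#' differentiation of bright lights), and `slope` in between — the only
#' region where luminance differences map to graded output. The bounds
#' themselves belong to the slope region (closed interval).
#'
#' @param luminance Luminances, cd/m2 (vectorized).
#' @param fit A converged, non-degenerate `crir_fit`.
#' @return Factor with levels `subthreshold`, `slope`, `saturation`.
#' @export
classify_region <- function(luminance, fit) {
  stopifnot(inherits(fit, "crir_fit"))
  if (!fit$converged || fit$degenerate) {
    stop("region classification requires a converged, non-degenerate fit",
         call. = FALSE)
  }
  if (any(!is.finite(luminance) | luminance <= 0)) {
    stop("`luminance` must be finite and > 0", call. = FALSE)
  }
  lo <- fit$region_bounds[["l_lo"]]
  hi <- fit$region_bounds[["l_hi"]]
  out <- ifelse(luminance < lo, "subthreshold",
                ifelse(luminance > hi, "saturation", "slope"))
  factor(out, levels = c("subthreshold", "slope", "saturation"))
}

#' Can two luminances be told apart under a fitted curve?
#'
#' Contrast between two luminances is resolvable only when the whole
#' interval lies in the slope region of the transfer curve; in the
#' subthreshold or saturation region the output difference vanishes.
#'
#' @param fit A converged `crir_fit`.
#' @param l1,l2 Two distinct luminances, cd/m2.
#' @return A one-row tibble with `resolvable` (logical) and
#'   `delta_amplitude` (volts, predicted output difference `|A(l2)-A(l1)|`).
#' @export
resolvable_contrast <- function(fit, l1, l2) {
  stopifnot(inherits(fit, "crir_fit"))
  if (!fit$converged || fit$degenerate) {
    stop("resolvable_contrast requires a converged, non-degenerate fit",
         call. = FALSE)
  }
  if (isTRUE(all.equal(l1, l2))) {
    stop("`l1` and `l2` must differ", call. = FALSE)
  }
  regions <- classify_region(c(l1, l2), fit)
  tibble::tibble(
    resolvable = all(regions == "slope"),
    delta_amplitude = abs(diff(predict(fit, c(l1, l2))))
  )
}
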