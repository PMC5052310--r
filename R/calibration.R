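#' Calibration constants for the knob-to-curve mapping
#'
#' The handheld power-supply unit exposes two knobs, `v_gl` (amplifier
#' sensitivity) and `v_bias` (amplifier gain), each an arbitrary integer from
#' 0 to 99. The true knob-voltage-to-curve mapping of the device is
#' proprietary and is in practice individualized per patient; this object
#' collects the package's default mapping as an explicit, swappable set of
#' calibration constants.
#'
#' The defaults encode:
#' * `v_gl` sweeps the curve midpoint linearly across `x_mid_span` = 4.5
#'   log10 cd/m2 starting at `x_mid_min` = -1, so the knob range covers the
#'   4--5 logarithmic units of luminance over which implant responses are
#'   measurable.
#' * `v_bias` sets the output swing through a Gaussian-shaped gain factor
#'   peaking at `v_bias_peak` = 65 (inside the 55--75 window where maximal
#'   in vivo output is typically found), with width `v_bias_sigma`.
#' * the chip-side saturation amplitude at the gain peak is `v_max_peak`
#'   volts; the corneal attenuation is derived so that the largest corneal
#'   response over the whole knob grid equals `corneal_peak_max` (35 mV).
#' * above `dark_onset` the dark (subthreshold) output rises quadratically,
#'   reproducing the clinically undesirable "elevated dark output" curves
#'   seen at high gain settings.
#' * the dimensionless slope at the gain peak is `log10(81)/2`, which makes
#'   the 10--90% dynamic range exactly 2.0 log10 units.
#'
#' @param x_mid_min Curve midpoint at `v_gl = 0`, log10 cd/m2.
#' @param x_mid_span Midpoint span over the full knob range, log10 units.
#' @param v_bias_peak Knob value at which the gain factor peaks.
#' @param v_bias_sigma Width (knob units) of the Gaussian gain factor.
#' @param v_max_peak Chip-side output swing (volts) at the gain peak.
#' @param v_min_base Baseline dark output (volts).
#' @param dark_onset `v_bias` value above which dark output starts rising.
#' @param dark_gain Fraction of `v_max_peak` the dark output reaches at
#'   `v_bias = 99`.
#' @param slope_peak Dimensionless logistic slope (per log10 unit) at the
#'   gain peak.
#' @param slope_floor Fraction of `slope_peak` retained as the gain factor
#'   tends to zero.
#' @param coupling_tau Electrode-tissue coupling time constant, seconds.
#' @param corneal_peak_max Largest corneal peak amplitude over the knob
#'   grid, volts; fixes the chip-to-cornea attenuation.
#'
#' @return An object of class `crir_calibration`: a named list of the
#'   constants above plus the derived `coupling_atten`.
#' @examples
#' cal <- crir_calibration()
#' cal$coupling_atten * (cal$v_min_base + cal$v_max_peak)  # 35 mV
#' @export
crir_calibration <- function(x_mid_min = -1.0,
                             x_mid_span = 4.5,
                             v_bias_peak = 65,
                             v_bias_sigma = 25,
                             v_max_peak = 2.0,
                             v_min_base = 0.002,
                             dark_onset = 70,
                             dark_gain = 0.3,
                             slope_peak = log10(81) / 2,
                             slope_floor = 0.3,
                             coupling_tau = 5e-4,
                             corneal_peak_max = 0.035) {
  stopifnot(
    x_mid_span > 0, v_bias_peak >= 0, v_bias_peak <= 99, v_bias_sigma > 0,
    v_max_peak > 0, v_min_base >= 0, dark_onset >= 0, dark_onset < 99,
    dark_gain >= 0, slope_peak > 0, slope_floor > 0, slope_floor <= 1,
    coupling_tau > 0, corneal_peak_max > 0
  )
  cal <- list(
    x_mid_min = x_mid_min, x_mid_span = x_mid_span,
    v_bias_peak = v_bias_peak, v_bias_sigma = v_bias_sigma,
    v_max_peak = v_max_peak, v_min_base = v_min_base,
    dark_onset = dark_onset, dark_gain = dark_gain,
    slope_peak = slope_peak, slope_floor = slope_floor,
    coupling_tau = coupling_tau, corneal_peak_max = corneal_peak_max,
    # attenuation so the grid-wide corneal maximum is corneal_peak_max:
    # the chip maximum over the grid is v_min_base + v_max_peak (gain peak,
    # no dark elevation there)
    coupling_atten = corneal_peak_max / (v_min_base + v_max_peak)
  )
  structure(cal, class = "crir_calibration")
}

#' @export
print.crir_calibration <- function(x, ...) {
  cat("<crir_calibration>\n")
  for (nm in names(x)) cat(sprintf("  %-16s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Serialize / restore calibration constants
#'
#' @param x A `crir_calibration` object (or for [as_crir_calibration()], a
#'   named list as produced by deserializing the JSON form).
#' @return `calibration_to_list()` returns a plain named list suitable for
#'   [jsonlite::write_json()]; `as_crir_calibration()` the restored object.
#' @export
calibration_to_list <- function(x) {
  stopifnot(inherits(x, "crir_calibration"))
  unclass(x)
}

#' @rdname calibration_to_list
#' @export
as_crir_calibration <- function(x) {
  if (inherits(x, "crir_calibration")) return(x)
  args <- x[setdiff(names(x), "coupling_atten")]
  do.call(crir_calibration, args)
}
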