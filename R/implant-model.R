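#' Knob settings of the handheld power-supply unit
#'
#' Both knobs take arbitrary integer values from 0 to 99. `v_gl` controls
#' the amplifiers' sensitivity (shifts the transfer curve along the
#' log-luminance axis); `v_bias` controls the gain (sets the maximal output).
#'
#' @param v_gl,v_bias Integer knob values in `[0, 99]`.
#' @return An object of class `knob_settings`.
#' @examples
#' knob_settings(20, 65)
#' @export
knob_settings <- function(v_gl = 20, v_bias = 65) {
  check_knob(v_gl, "v_gl")
  check_knob(v_bias, "v_bias")
  structure(list(v_gl = as.integer(v_gl), v_bias = as.integer(v_bias)),
            class = "knob_settings")
}

check_knob <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x != round(x) || x < 0 || x > 99) {
    stop(sprintf("`%s` must be a single integer in [0, 99], got %s",
                 name, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.knob_settings <- function(x, ...) {
  cat(sprintf("<knob_settings> v_gl = %d, v_bias = %d\n", x$v_gl, x$v_bias))
  invisible(x)
}

#' @export
format.knob_settings <- function(x, ...) sprintf("%d/%d", x$v_gl, x$v_bias)

gain_factor <- function(v_bias, calibration) {
  exp(-0.5 * ((v_bias - calibration$v_bias_peak) / calibration$v_bias_sigma)^2)
}

#' Map knob settings to transfer-curve parameters
#'
#' Converts `v_gl`/`v_bias` knob values into the four parameters of the
#' implant's sigmoidal luminance-to-voltage transfer characteristic under a
#' given calibration. `x_mid` is a strictly increasing affine function of
#' `v_gl`; the output swing `v_max - v_min` follows a Gaussian-shaped gain
#' factor in `v_bias` peaking at the calibration's `v_bias_peak`; the dark
#' output `v_min` rises above `dark_onset`; the dimensionless slope scales
#' affinely with the gain factor (floor `slope_floor`).
#'
#' Inputs are vectorized and recycled, so a whole settings grid can be
#' mapped in one call.
#'
#' @param v_gl,v_bias Integer knob values in `[0, 99]` (vectors allowed), or
#'   a [knob_settings()] object as the first argument.
#' @param calibration A [crir_calibration()] object.
#' @return A tibble of class `transfer_params` with one row per setting and
#'   columns `v_gl`, `v_bias`, `v_min`, `v_max` (volts, chip side), `x_mid`
#'   (log10 cd/m2) and `slope` (per log10 unit).
#' @examples
#' knob_to_params(20, 65)
#' knob_to_params(v_gl = c(20, 30), v_bias = 65)
#' @export
knob_to_params <- function(v_gl, v_bias = NULL, calibration = crir_calibration()) {
  if (inherits(v_gl, "knob_settings")) {
    settings <- v_gl
    v_gl <- settings$v_gl
    v_bias <- settings$v_bias
  }
  stopifnot(inherits(calibration, "crir_calibration"))
  if (length(v_gl) == 0 || length(v_bias) == 0) {
    stop("`v_gl` and `v_bias` must be non-empty", call. = FALSE)
  }
  bad <- function(x) any(!is.finite(x) | x != round(x) | x < 0 | x > 99)
  if (bad(v_gl) || bad(v_bias)) {
    stop("knob values must be integers in [0, 99]", call. = FALSE)
  }
  n <- max(length(v_gl), length(v_bias))
  v_gl <- rep_len(as.integer(v_gl), n)
  v_bias <- rep_len(as.integer(v_bias), n)

  g <- gain_factor(v_bias, calibration)
  dark_rise <- pmax(0, (v_bias - calibration$dark_onset) /
                      (99 - calibration$dark_onset))^2
  v_min <- calibration$v_min_base +
    calibration$dark_gain * calibration$v_max_peak * dark_rise
  v_max <- v_min + calibration$v_max_peak * g
  out <- tibble::tibble(
    v_gl = v_gl,
    v_bias = v_bias,
    v_min = v_min,
    v_max = v_max,
    x_mid = calibration$x_mid_min + calibration$x_mid_span * (v_gl / 99),
    slope = calibration$slope_peak *
      (calibration$slope_floor + (1 - calibration$slope_floor) * g)
  )
  class(out) <- c("transfer_params", class(out))
  out
}

#' Construct transfer-curve parameters directly
#'
#' Builds a `transfer_params` row from explicit values, bypassing the knob
#' mapping (useful for fitted curves and constructed test cases).
#'
#' @param v_min,v_max Dark and saturation outputs, volts; `v_max >= v_min >= 0`.
#' @param x_mid Curve midpoint, log10 cd/m2.
#' @param slope Dimensionless logistic slope per log10 unit; `> 0`.
#' @return A one-row `transfer_params` tibble (with `v_gl`/`v_bias` set to `NA`).
#' @export
transfer_params <- function(v_min, v_max, x_mid, slope) {
  stopifnot(
    is.finite(v_min), is.finite(v_max), is.finite(x_mid), is.finite(slope),
    v_min >= 0, v_max >= v_min, slope > 0
  )
  out <- tibble::tibble(v_gl = NA_integer_, v_bias = NA_integer_,
                        v_min = v_min, v_max = v_max,
                        x_mid = x_mid, slope = slope)
  class(out) <- c("transfer_params", class(out))
  out
}

#' Implant output voltage for a given luminance
#'
#' Evaluates the sigmoidal transfer characteristic: a four-parameter
#' base-10 logistic in log10 luminance,
#' `V(L) = v_min + (v_max - v_min) / (1 + 10^(-slope * (log10(L) - x_mid)))`.
#' Output is monotone nondecreasing in luminance and bounded by
#' `[v_min, v_max]`.
#'
#' @param luminance Luminance in cd/m2, strictly positive (vectorized).
#' @param params A one-row `transfer_params` tibble (from [knob_to_params()]
#'   or [transfer_params()]).
#' @return Numeric vector of output voltages (volts), same length as
#'   `luminance`.
#' @examples
#' p <- knob_to_params(20, 65)
#' transfer_voltage(10^p$x_mid, p) == (p$v_min + p$v_max) / 2
#' @export
transfer_voltage <- function(luminance, params) {
  stopifnot(inherits(params, "transfer_params"), nrow(params) == 1)
  if (any(!is.finite(luminance) | luminance <= 0)) {
    stop("`luminance` must be finite and > 0 (cd/m2)", call. = FALSE)
  }
  z <- params$slope * (log10(luminance) - params$x_mid)
  params$v_min + (params$v_max - params$v_min) / (1 + 10^(-z))
}

#' Dynamic range of a transfer curve
#'
#' Computes the luminance bounds where the output crosses
#' `v_min + frac * (v_max - v_min)` for `frac = lo_frac` and `hi_frac`, and
#' their log10 difference, in closed form from the logistic inverse. The
#' span between the 10% and 90% crossings is the curve's dynamic range: the
#' luminance range translated into a graded output, within which contrast
#' can be resolved.
#'
#' @param params A one-row `transfer_params` tibble.
#' @param lo_frac,hi_frac Fractions of the output swing, `0 < lo <= hi < 1`.
#' @return A one-row tibble with `l_lo`, `l_hi` (cd/m2), `span_log10` and a
#'   `degenerate` flag. A flat curve (`v_max == v_min`) is flagged
#'   degenerate with `NA` bounds rather than raising an error.
#' @examples
#' dynamic_range(knob_to_params(20, 65))  # span_log10 == 2 at defaults
#' @export
dynamic_range <- function(params, lo_frac = 0.1, hi_frac = 0.9) {
  stopifnot(inherits(params, "transfer_params"), nrow(params) == 1)
  if (!(lo_frac > 0 && hi_frac < 1 && lo_frac <= hi_frac)) {
    stop("need 0 < lo_frac <= hi_frac < 1", call. = FALSE)
  }
  if (!is.finite(params$slope) || params$slope <= 0 ||
      (params$v_max - params$v_min) <= 0) {
    return(tibble::tibble(l_lo = NA_real_, l_hi = NA_real_,
                          span_log10 = NA_real_, degenerate = TRUE))
  }
  logit10 <- function(f) log10(f / (1 - f))
  x_lo <- params$x_mid + logit10(lo_frac) / params$slope
  x_hi <- params$x_mid + logit10(hi_frac) / params$slope
  tibble::tibble(l_lo = 10^x_lo, l_hi = 10^x_hi,
                 span_log10 = x_hi - x_lo, degenerate = FALSE)
}
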