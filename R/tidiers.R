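#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted transfer curve
#'
#' @param x A `crir_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`, `unit`.
#' @method tidy crir_fit
#' @export
tidy.crir_fit <- function(x, ...) {
  if (!x$converged || x$degenerate) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          unit = character()))
  }
  p <- x$params
  tibble::tibble(
    term = c("v_min", "v_max", "x_mid", "slope"),
    estimate = c(p$v_min, p$v_max, p$x_mid, p$slope),
    unit = c("V", "V", "log10 cd/m2", "per log10 unit")
  )
}

#' One-row summary of a fitted transfer curve
#'
#' @param x A `crir_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `converged`, `degenerate`, `v_max`,
#'   `dynamic_range`, `l_lo`, `l_hi`, `rmse`, `n_points`.
#' @method glance crir_fit
#' @export
glance.crir_fit <- function(x, ...) {
  ok <- x$converged && !x$degenerate
  tibble::tibble(
    converged = x$converged,
    degenerate = x$degenerate,
    v_max = if (ok) x$params$v_max else NA_real_,
    dynamic_range = if (ok) x$dynamic_range else NA_real_,
    l_lo = if (ok) x$region_bounds[["l_lo"]] else NA_real_,
    l_hi = if (ok) x$region_bounds[["l_hi"]] else NA_real_,
    rmse = x$rmse,
    n_points = nrow(x$curve)
  )
}

#' Plot a recorded trace
#'
#' @param object A `crir_wave`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot crir_wave
#' @export
autoplot.crir_wave <- function(object, ...) {
  vcol <- setdiff(names(object), c("time", "i_chip", "clipped"))[1]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time,
                                       y = .data[[vcol]] * 1e3)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "voltage (mV)") +
    ggplot2::theme_minimal()
}

#' Plot a response curve
#'
#' @param object A `crir_curve`.
#' @param ... Unused.
#' @return A ggplot of amplitude (mV) against luminance on a log axis.
#' @method autoplot crir_curve
#' @export
autoplot.crir_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$luminance,
                                       y = .data$amplitude * 1e3)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "luminance (cd/m2)", y = "amplitude (mV)") +
    ggplot2::theme_minimal()
}

#' Plot a fitted transfer curve with region shading
#'
#' Shows the measured amplitudes, the fitted logistic, and the
#' subthreshold / slope / saturation segmentation at the fit's 10%/90%
#' crossings.
#'
#' @param object A converged `crir_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot crir_fit
#' @export
autoplot.crir_fit <- function(object, ...) {
  stopifnot(object$converged, !object$degenerate)
  curve <- object$curve
  lgrid <- 10^seq(log10(min(curve$luminance)), log10(max(curve$luminance)),
                  length.out = 200)
  pred <- tibble::tibble(luminance = lgrid,
                         amplitude = predict(object, lgrid))
  lo <- object$region_bounds[["l_lo"]]
  hi <- object$region_bounds[["l_hi"]]
  shade <- tibble::tibble(
    xmin = c(min(curve$luminance), max(lo, min(curve$luminance)),
             min(hi, max(curve$luminance))),
    xmax = c(max(lo, min(curve$luminance)), min(hi, max(curve$luminance)),
             max(curve$luminance)),
    region = factor(c("subthreshold", "slope", "saturation"),
                    levels = c("subthreshold", "slope", "saturation"))
  )
  ggplot2::ggplot() +
    ggplot2::geom_rect(data = shade,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf,
                                    fill = .data$region), alpha = 0.15) +
    ggplot2::geom_line(data = pred,
                       ggplot2::aes(x = .data$luminance,
                                    y = .data$amplitude * 1e3)) +
    ggplot2::geom_point(data = curve,
                        ggplot2::aes(x = .data$luminance,
                                     y = .data$amplitude * 1e3)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "luminance (cd/m2)", y = "amplitude (mV)",
                  fill = "region") +
    ggplot2::theme_minimal()
}

#' Plot a family of fitted curves
#'
#' One fitted transfer curve per knob-setting combination, the usual way a
#' measurement session is summarized.
#'
#' @param family A `crir_family`.
#' @return A ggplot.
#' @export
plot_curve_family <- function(family) {
  stopifnot(inherits(family, "crir_family"))
  dat <- purrr::map_dfr(seq_len(nrow(family)), function(i) {
    f <- family$fit[[i]]
    if (!family$converged[i]) return(NULL)
    lgrid <- 10^seq(log10(min(f$curve$luminance)),
                    log10(max(f$curve$luminance)), length.out = 150)
    tibble::tibble(
      setting = sprintf("%d/%d", family$v_gl[i], family$v_bias[i]),
      luminance = lgrid, amplitude = predict(f, lgrid))
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$luminance,
                                    y = .data$amplitude * 1e3,
                                    colour = .data$setting)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "luminance (cd/m2)", y = "amplitude (mV)",
                  colour = "v_gl/v_bias") +
    ggplot2::theme_minimal()
}
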