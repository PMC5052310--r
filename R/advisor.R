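#' Collect fitted curves into a settings family
#'
#' A patient's measurement session yields several response curves, one per
#' `v_gl`/`v_bias` combination. This constructor collects their fits into a
#' family for the settings advisor.
#'
#' @param fits A list of `crir_fit` objects, each carrying its
#'   [knob_settings()] (as produced by the analysis pipeline).
#' @return A tibble of class `crir_family` with columns `v_gl`, `v_bias`,
#'   `converged` and a `fit` list-column.
#' @export
as_crir_family <- function(fits) {
  stopifnot(length(fits) >= 1, all(purrr::map_lgl(fits, inherits, "crir_fit")))
  settings <- purrr::map(fits, "settings")
  if (any(purrr::map_lgl(settings, is.null))) {
    stop("every fit in a family must carry its knob settings", call. = FALSE)
  }
  fam <- tibble::tibble(
    v_gl = purrr::map_int(settings, "v_gl"),
    v_bias = purrr::map_int(settings, "v_bias"),
    converged = purrr::map_lgl(fits, function(f) f$converged && !f$degenerate),
    fit = fits
  )
  if (anyDuplicated(fam[c("v_gl", "v_bias")])) {
    stop("duplicate knob settings in family", call. = FALSE)
  }
  if (!any(fam$converged)) {
    stop("a family needs at least one converged fit", call. = FALSE)
  }
  class(fam) <- c("crir_family", class(fam))
  fam
}

#' Recommend knob settings for an ambient luminance range
#'
#' Implements the lowest-necessary-output selection rules over a family of
#' fitted curves:
#' 1. a curve *qualifies* when its slope region fully contains the ambient
#'    luminance interval (contrast in that environment falls on the steep
#'    part of the sigmoid);
#' 2. curves whose fitted output at the dark reference luminance exceeds
#'    `dark_frac` of the family-wide maximum output are *rejected* as
#'    having elevated dark output (they stimulate continuously in the dark
#'    and compress the contrast range);
#' 3. among the remaining curves the one with the lowest saturation output
#'    `v_max` is chosen (lowest voltage that still covers the environment);
#'    ties break by lower dark output, then lower `v_bias`.
#'
#' Qualifying curves that lose only on rule 3 stay in the qualifying set,
#' annotated with a `high_saturation_output` note.
#'
#' @param family A [as_crir_family()] object.
#' @param ambient Length-2 numeric, the ambient luminance interval cd/m2.
#' @param dark_luminance Dark reference luminance, cd/m2.
#' @param dark_frac Rejection threshold as a fraction of the family-wide
#'   maximum output.
#' @return An object of class `crir_recommendation`: list with `chosen`
#'   ([knob_settings()] or `NULL` when nothing qualifies), `qualifying` and
#'   `rejected` tibbles (the latter with a `reason` column from
#'   `no_coverage` / `elevated_dark_output`), and the inputs used. Every
#'   family entry appears exactly once across the two tibbles.
#' @export
recommend_settings <- function(family, ambient, dark_luminance = 0.1,
                               dark_frac = 0.1) {
  stopifnot(inherits(family, "crir_family"))
  if (!(length(ambient) == 2 && all(is.finite(ambient)) && all(ambient > 0) &&
        ambient[1] < ambient[2])) {
    stop("`ambient` must be a positive increasing luminance interval",
         call. = FALSE)
  }
  ev <- purrr::map_dfr(seq_len(nrow(family)), function(i) {
    f <- family$fit[[i]]
    ok <- family$converged[i]
    tibble::tibble(
      v_gl = family$v_gl[i], v_bias = family$v_bias[i],
      converged = ok,
      v_max = if (ok) f$params$v_max else NA_real_,
      l_lo = if (ok) f$region_bounds[["l_lo"]] else NA_real_,
      l_hi = if (ok) f$region_bounds[["l_hi"]] else NA_real_,
      dark_output = if (ok) predict(f, dark_luminance) else NA_real_
    )
  })
  family_max <- max(ev$v_max, na.rm = TRUE)
  ev <- ev |>
    dplyr::mutate(
      covers = .data$converged & .data$l_lo <= ambient[1] &
        .data$l_hi >= ambient[2],
      elevated_dark = .data$converged &
        .data$dark_output > dark_frac * family_max
    )
  rejected <- ev |>
    dplyr::filter(!.data$covers | .data$elevated_dark) |>
    dplyr::mutate(reason = dplyr::case_when(
      !.data$covers ~ "no_coverage",
      .data$elevated_dark ~ "elevated_dark_output"
    ))
  # ties in the continuous criteria are taken at 6 significant digits, so
  # curves with numerically indistinguishable outputs fall through to the
  # next tie-break instead of being ordered by fitting noise
  qualifying <- ev |>
    dplyr::filter(.data$covers, !.data$elevated_dark) |>
    dplyr::arrange(signif(.data$v_max, 6), signif(.data$dark_output, 6),
                   .data$v_bias)
  chosen <- NULL
  if (nrow(qualifying) > 0) {
    chosen <- knob_settings(qualifying$v_gl[1], qualifying$v_bias[1])
    qualifying$note <- c("chosen",
                         rep("high_saturation_output",
                             nrow(qualifying) - 1))
  }
  structure(list(chosen = chosen, qualifying = qualifying,
                 rejected = rejected, ambient = ambient,
                 dark_luminance = dark_luminance, dark_frac = dark_frac),
            class = "crir_recommendation")
}

#' @export
print.crir_recommendation <- function(x, ...) {
  cat("<crir_recommendation>\n")
  cat(sprintf("  ambient %.3g .. %.3g cd/m2, dark ref %.3g cd/m2\n",
              x$ambient[1], x$ambient[2], x$dark_luminance))
  if (is.null(x$chosen)) {
    cat("  no qualifying settings\n")
  } else {
    cat("  chosen:", format(x$chosen), "\n")
  }
  if (nrow(x$rejected)) {
    cat("  rejected:\n")
    for (i in seq_len(nrow(x$rejected))) {
      cat(sprintf("    %d/%d: %s\n", x$rejected$v_gl[i], x$rejected$v_bias[i],
                  x$rejected$reason[i]))
    }
  }
  invisible(x)
}

#' Rule-based device fault triage
#'
#' Distinguishes technical from biological failure after a sudden loss of
#' perception, from response amplitudes recorded across gaze directions:
#' * no gaze condition shows a detectable pulse (amplitude at least
#'   `k * noise_rms`) — `device_output_absent` (e.g. a damaged cable: no
#'   responses are measurable at all);
#' * responses are detectable in some but not all gaze directions, or come
#'   and go across repeats within a direction — `gaze_dependent_intermittent`
#'   (typical of a loose cable connection);
#' * responses are present and stable everywhere — `device_functional`
#'   (a persisting perception problem then points to a biological cause,
#'   outside the scope of a device test).
#'
#' @param measurements A data frame with columns `condition` (gaze
#'   direction label), `rep` (repeat index within condition) and
#'   `amplitude` (volts); one row per pulse or per repeat.
#' @param noise_rms Noise RMS of the recording, volts.
#' @param k Detection threshold multiplier.
#' @return An object of class `crir_diagnosis`: list with `status`,
#'   `evidence` (per-condition detection summary), `threshold` and `note`.
#'   The status is re-derivable from the evidence table alone.
#' @export
diagnose_device <- function(measurements, noise_rms = 20e-6, k = 5) {
  if (is.null(measurements) || nrow(measurements) == 0) {
    stop("`measurements` must contain at least one gaze condition",
         call. = FALSE)
  }
  stopifnot(all(c("condition", "rep", "amplitude") %in% names(measurements)))
  threshold <- k * noise_rms
  evidence <- measurements |>
    dplyr::group_by(.data$condition, .data$rep) |>
    dplyr::summarise(detected = any(abs(.data$amplitude) >= threshold),
                     max_amplitude = max(abs(.data$amplitude)),
                     .groups = "drop") |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n_reps = dplyr::n(),
                     n_detected = sum(.data$detected),
                     detect_rate = mean(.data$detected),
                     max_amplitude = max(.data$max_amplitude),
                     .groups = "drop")
  any_detected <- any(evidence$n_detected > 0)
  all_conditions <- all(evidence$n_detected > 0)
  intermittent <- any(evidence$n_detected > 0 &
                        evidence$n_detected < evidence$n_reps)
  status <- if (!any_detected) {
    "device_output_absent"
  } else if (!all_conditions || intermittent) {
    "gaze_dependent_intermittent"
  } else {
    "device_functional"
  }
  note <- if (status == "device_functional") {
    paste("stable output in all gaze directions; a persisting perception",
          "problem would point to a biological cause, which this device",
          "test cannot assess")
  } else NULL
  structure(list(status = status, evidence = evidence,
                 threshold = threshold, k = k, noise_rms = noise_rms,
                 note = note),
            class = "crir_diagnosis")
}

#' @export
print.crir_diagnosis <- function(x, ...) {
  cat("<crir_diagnosis>", x$status, "\n")
  cat(sprintf("  detection threshold %.3g V (%g x noise RMS)\n",
              x$threshold, x$k))
  print(x$evidence, ...)
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

#' Check recording equipment against the method's requirements
#'
#' Standard clinical ERG equipment suffices for implant-response
#' recordings provided: sampling of at least 1 kHz (5 kHz recommended, the
#' implant pulse lasts only 1 ms); unclipped headroom for corneal pulses
#' of up to 35 mV at the amplifier input; and a stimulator reaching at
#' least 500 cd/m2 to probe the luminances of daily living.
#'
#' @param config A [recording_config()] object.
#' @param stimulator_max Maximal stimulator luminance, cd/m2.
#' @param max_signal Largest expected corneal amplitude, volts.
#' @return A tibble with one row per requirement: `item`, `requirement`,
#'   `value`, `pass`.
#' @export
check_equipment <- function(config = recording_config(),
                            stimulator_max = 1000, max_signal = 0.035) {
  headroom <- config$input_range / config$amp_gain
  tibble::tibble(
    item = c("sampling_rate", "amplitude_headroom", "stimulator_luminance"),
    requirement = c(">= 1000 Hz (5000 recommended)",
                    sprintf(">= %g V at input", max_signal),
                    ">= 500 cd/m2"),
    value = c(config$sampling_rate, headroom, stimulator_max),
    pass = c(config$sampling_rate >= 1000,
             headroom >= max_signal,
             stimulator_max >= 500)
  )
}
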