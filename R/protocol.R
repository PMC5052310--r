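#' Build a luminance-step flash protocol
#'
#' Generates the full-field flash series used to measure the implant's
#' transfer characteristic: long-duration flashes of geometrically
#' increasing luminance, `l_min * 10^(k * log_step)` for
#' `k = 0 .. floor(log10(l_max / l_min) / log_step)`. The defaults realize
#' the clinical series: 9 flashes of 350 ms from 0.1 to 1000 photopic
#' cd/m2 in 0.5 log steps.
#'
#' @param l_min,l_max First and maximal luminance, cd/m2 (`l_max` is reached
#'   exactly only when `log10(l_max/l_min)` is a multiple of `log_step`).
#' @param log_step Spacing between consecutive flashes, log10 units.
#' @param flash_duration Flash duration, seconds.
#' @param inter_step_interval Darkness between flash offset and the next
#'   onset, seconds. The 2 s default lets the band-pass filter settle
#'   between steps.
#' @param lead_in Darkness before the first flash, seconds (provides the
#'   pre-pulse baseline for the first step).
#' @return An object of class `stim_protocol`: a list with a `steps` tibble
#'   (`step`, `luminance`, `log10_luminance`, `onset`, `offset`, seconds),
#'   the timing scalars above and the total `duration`.
#' @examples
#' build_protocol()          # 9 steps, 0.1 .. 1000 cd/m2
#' build_protocol(1, 1, 0.5) # single step
#' @export
build_protocol <- function(l_min = 0.1, l_max = 1000, log_step = 0.5,
                           flash_duration = 0.35, inter_step_interval = 2,
                           lead_in = 0.5) {
  if (!(is.finite(l_min) && l_min > 0) || !(is.finite(l_max) && l_max >= l_min) ||
      !(is.finite(log_step) && log_step > 0) ||
      !(flash_duration > 0) || !(inter_step_interval >= 0) || !(lead_in >= 0)) {
    stop("invalid protocol arguments: need l_max >= l_min > 0, log_step > 0, ",
         "positive durations", call. = FALSE)
  }
  n_steps <- floor(log10(l_max / l_min) / log_step + 1e-9) + 1
  k <- seq_len(n_steps) - 1
  luminance <- l_min * 10^(k * log_step)
  onset <- lead_in + k * (flash_duration + inter_step_interval)
  steps <- tibble::tibble(
    step = seq_len(n_steps),
    luminance = luminance,
    log10_luminance = log10(l_min) + k * log_step,
    onset = onset,
    offset = onset + flash_duration
  )
  structure(list(
    steps = steps,
    flash_duration = flash_duration,
    inter_step_interval = inter_step_interval,
    lead_in = lead_in,
    duration = max(steps$offset) + inter_step_interval
  ), class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "<stim_protocol> %d steps, %.3g .. %.3g cd/m2, flash %.0f ms, ISI %.1f s\n",
    nrow(x$steps), min(x$steps$luminance), max(x$steps$luminance),
    x$flash_duration * 1000, x$inter_step_interval))
  print(x$steps, ...)
  invisible(x)
}

#' Expected chip pulse times within each flash
#'
#' The chip free-runs at its working frequency (it is not synchronized to
#' the stimulator), emitting one pulse per frame. During a flash of
#' duration `d` starting at phase offset `phase` into the chip's cycle, the
#' pulses that begin inside the flash window fall at
#' `onset + phase + k / f`, `k = 0, 1, ...`; at the 350 ms / 5 Hz defaults
#' this yields one or two pulses per flash depending on phase.
#'
#' @param protocol A [build_protocol()] object.
#' @param chip A [chip_config()] object (supplies the working frequency).
#' @param phase Offset of the first chip frame after flash onset, seconds,
#'   in `[0, 1/working_frequency)`.
#' @return A tibble with `step`, `luminance`, `pulse_index` and `time`
#'   (pulse onset, seconds).
#' @examples
#' nrow(expected_pulse_times(build_protocol()))  # 2 pulses x 9 steps
#' @export
expected_pulse_times <- function(protocol, chip = chip_config(), phase = 0) {
  stopifnot(inherits(protocol, "stim_protocol"), inherits(chip, "chip_config"))
  period <- 1 / chip$working_frequency
  if (!(phase >= 0 && phase < period)) {
    stop("`phase` must lie in [0, 1/working_frequency)", call. = FALSE)
  }
  d <- protocol$flash_duration
  n_pulses <- max(0L, ceiling((d - phase) / period - 1e-12))
  purrr::map_dfr(seq_len(nrow(protocol$steps)), function(i) {
    row <- protocol$steps[i, ]
    k <- seq_len(n_pulses) - 1
    tibble::tibble(
      step = row$step,
      luminance = row$luminance,
      pulse_index = k + 1L,
      time = row$onset + phase + k * period
    )
  })
}
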