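SCHEMA_VERSION <- "1.0"

protocol_to_list <- function(p) {
  list(l_min = min(p$steps$luminance), l_max = max(p$steps$luminance),
       log_step = if (nrow(p$steps) > 1)
         diff(p$steps$log10_luminance[1:2]) else 0.5,
       flash_duration = p$flash_duration,
       inter_step_interval = p$inter_step_interval,
       lead_in = p$lead_in)
}

config_to_list <- function(cfg) unclass(cfg)

meta_to_list <- function(meta) {
  out <- list(schema_version = SCHEMA_VERSION, units = list(
    time = "s", voltage = "V (referred to amplifier input)",
    luminance = "cd/m2", log_base = 10))
  if (!is.null(meta$protocol)) out$protocol <- protocol_to_list(meta$protocol)
  if (!is.null(meta$settings)) out$settings <- unclass(meta$settings)
  if (!is.null(meta$chip)) out$chip <- unclass(meta$chip)
  if (!is.null(meta$config)) out$config <- unclass(meta$config)
  if (!is.null(meta$calibration))
    out$calibration <- calibration_to_list(meta$calibration)
  if (!is.null(meta$phase)) out$phase <- meta$phase
  if (!is.null(meta$noise_seed)) out$noise_seed <- meta$noise_seed
  if (!is.null(meta$output_scale)) out$output_scale <- meta$output_scale
  if (!is.null(meta$artifact_windows) && nrow(meta$artifact_windows) > 0)
    out$artifact_windows <- meta$artifact_windows
  out
}

meta_from_list <- function(x) {
  meta <- list()
  if (!is.null(x$protocol)) meta$protocol <- do.call(build_protocol, x$protocol)
  if (!is.null(x$settings))
    meta$settings <- knob_settings(x$settings$v_gl, x$settings$v_bias)
  if (!is.null(x$chip)) meta$chip <- do.call(chip_config, x$chip)
  if (!is.null(x$config)) meta$config <- do.call(recording_config, x$config)
  if (!is.null(x$calibration))
    meta$calibration <- as_crir_calibration(x$calibration)
  if (!is.null(x$phase)) meta$phase <- x$phase
  if (!is.null(x$noise_seed)) meta$noise_seed <- x$noise_seed
  if (!is.null(x$output_scale)) meta$output_scale <- x$output_scale
  if (!is.null(x$artifact_windows))
    meta$artifact_windows <- tibble::as_tibble(x$artifact_windows)
  meta
}

#' Write / read a recorded trace
#'
#' Traces are stored as plain CSV with header columns `time_s`, `voltage_v`
#' (seconds; volts referred to the amplifier input) plus a JSON sidecar
#' (`<path>.json`) carrying the metadata: protocol, knob settings, chip and
#' recording configuration, calibration, artifact labels and the noise
#' seed. The round trip is lossless for the samples (written at full
#' precision) and for the metadata.
#'
#' @param trace A `crir_wave` trace.
#' @param path CSV file path; the sidecar is written next to it.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` the
#'   reconstructed trace.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "crir_wave"))
  vcol <- setdiff(names(trace), c("time", "i_chip", "clipped"))[1]
  readr::write_csv(tibble::tibble(time_s = trace$time,
                                  voltage_v = trace[[vcol]]), path)
  jsonlite::write_json(meta_to_list(wave_meta(trace)),
                       paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "d"),
                        progress = FALSE)
  req <- c("time_s", "voltage_v")
  if (!all(req %in% names(df))) {
    stop(sprintf("trace file '%s' lacks required columns %s", path,
                 paste(setdiff(req, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1] + 1
    stop(sprintf("non-increasing time at line %d of '%s'", bad + 1, path),
         call. = FALSE)
  }
  if (length(dt) > 1 && max(abs(dt - stats::median(dt))) >
        1e-6 * stats::median(dt)) {
    bad <- which.max(abs(dt - stats::median(dt))) + 1
    stop(sprintf("non-uniform sampling at line %d of '%s'", bad + 1, path),
         call. = FALSE)
  }
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    meta_from_list(jsonlite::read_json(sidecar, simplifyVector = TRUE))
  } else list()
  out <- new_wave(df$time_s, df$voltage_v, "voltage", "filtered", meta)
  out
}

fit_to_list <- function(fit) {
  out <- list(converged = fit$converged, degenerate = fit$degenerate)
  if (!is.null(fit$settings)) out$settings <- unclass(fit$settings)
  if (fit$converged && !fit$degenerate) {
    p <- fit$params
    out$params <- list(v_min = p$v_min, v_max = p$v_max,
                       x_mid = p$x_mid, slope = p$slope)
    out$region_bounds <- as.list(fit$region_bounds)
    out$dynamic_range <- fit$dynamic_range
    out$rmse <- fit$rmse
  }
  if (!is.null(fit$note)) out$note <- fit$note
  out
}

#' Generate a seeded synthetic session
#'
#' Produces a complete, labeled session bundle for a named scenario, with
#' every trace simulated through the full signal chain and the generating
#' ground truth embedded for downstream checks:
#'
#' * `clean_family` — six clean curves on a `v_gl` x `v_bias` grid;
#' * `vgl_sweep` — fixed gain, `v_gl` swept (curves are horizontal
#'   translations, fitted `x_mid` increases with `v_gl`);
#' * `vbias_sweep` — fixed sensitivity, `v_bias` swept (fitted `v_max`
#'   peaks inside the 55--75 knob window);
#' * `elevated_dark` — family including high-`v_bias` curves with raised
#'   dark output, exercising the advisor's rejection rule;
#' * `broken_wire` — no device output in any gaze direction;
#' * `loose_connection` — output present in only some gaze directions and
#'   intermittent across repeats;
#' * `artifact_heavy` — one step fully corrupted by labeled blink
#'   artifacts plus a clean repeat trace for it.
#'
#' @param scenario Scenario name (see above).
#' @param seed Integer master seed; every stochastic element derives from it.
#' @param noise_rms Noise level, volts RMS at the amplifier input.
#' @return A list of class `crir_bundle`: `scenario`, `seed`, `protocol`,
#'   `chip`, `config`, `calibration`, and `entries` — a list of records
#'   with `settings`, `condition`, `rep`, `trace`, optional `repeat_trace`,
#'   and `truth`.
#' @export
generate_fixture <- function(scenario, seed = 1L, noise_rms = 20e-6) {
  scenarios <- c("clean_family", "vgl_sweep", "vbias_sweep", "elevated_dark",
                 "broken_wire", "loose_connection", "artifact_heavy")
  if (!scenario %in% scenarios) {
    stop(sprintf("unknown scenario '%s'; available: %s", scenario,
                 paste(scenarios, collapse = ", ")), call. = FALSE)
  }
  seed <- as.integer(seed)
  protocol <- build_protocol()
  chip <- chip_config()
  calibration <- crir_calibration()
  config <- recording_config(noise_rms = noise_rms, seed = seed)

  sim <- function(settings, offset, scale = 1, artifacts = NULL) {
    simulate_recording(protocol, settings, chip, config, calibration,
                       artifacts = artifacts, seed_offset = offset,
                       output_scale = scale)
  }
  entry <- function(settings, trace, condition = NA_character_, rep = 1L,
                    truth = list(), repeat_trace = NULL) {
    list(settings = settings, condition = condition, rep = rep,
         trace = trace, repeat_trace = repeat_trace, truth = truth)
  }

  entries <- switch(
    scenario,
    clean_family = {
      grid <- expand.grid(v_gl = c(10, 30, 50), v_bias = c(45, 65))
      purrr::map(seq_len(nrow(grid)), function(i) {
        s <- knob_settings(grid$v_gl[i], grid$v_bias[i])
        entry(s, sim(s, i), truth = list(
          params = knob_to_params(s, calibration = calibration)))
      })
    },
    vgl_sweep = {
      v_gls <- c(0, 20, 40, 60, 80, 99)
      purrr::map(seq_along(v_gls), function(i) {
        s <- knob_settings(v_gls[i], 65)
        entry(s, sim(s, i), truth = list(
          params = knob_to_params(s, calibration = calibration)))
      })
    },
    vbias_sweep = {
      v_biases <- c(5, 20, 35, 50, 65, 80, 95)
      purrr::map(seq_along(v_biases), function(i) {
        s <- knob_settings(40, v_biases[i])
        entry(s, sim(s, i), truth = list(
          params = knob_to_params(s, calibration = calibration)))
      })
    },
    elevated_dark = {
      grid <- expand.grid(v_gl = c(20, 45), v_bias = c(65, 85, 95))
      purrr::map(seq_len(nrow(grid)), function(i) {
        s <- knob_settings(grid$v_gl[i], grid$v_bias[i])
        p <- knob_to_params(s, calibration = calibration)
        entry(s, sim(s, i), truth = list(
          params = p,
          elevated_dark = grid$v_bias[i] > calibration$dark_onset))
      })
    },
    broken_wire = {
      conditions <- c("center", "left", "right")
      s <- knob_settings(20, 65)
      idx <- 0
      purrr::flatten(purrr::map(conditions, function(cond) {
        purrr::map(1:2, function(r) {
          idx <<- idx + 1
          entry(s, sim(s, idx, scale = 0), condition = cond, rep = r,
                truth = list(status = "device_output_absent"))
        })
      }))
    },
    loose_connection = {
      conditions <- c("center", "up", "down", "left", "right")
      s <- knob_settings(20, 65)
      present <- withr::with_seed(seed, sort(sample(conditions, 2)))
      idx <- 0
      purrr::flatten(purrr::map(conditions, function(cond) {
        purrr::map(1:2, function(r) {
          idx <<- idx + 1
          # in one "present" condition the contact only holds on rep 1:
          # intermittent within-condition presence
          scale <- if (!cond %in% present) 0
          else if (cond == present[1] && r == 2) 0 else 1
          entry(s, sim(s, idx, scale = scale), condition = cond, rep = r,
                truth = list(status = "gaze_dependent_intermittent",
                             present = cond %in% present))
        })
      }))
    },
    artifact_heavy = {
      s <- knob_settings(20, 65)
      # blink artifacts covering every pulse of step 5, plus stray blinks
      step5 <- protocol$steps[5, ]
      arts <- list(
        list(type = "blink", time = step5$onset - 0.05, duration = 0.45,
             amplitude = 3e-3),
        list(type = "blink", time = protocol$steps$onset[2] + 0.1,
             duration = 0.15, amplitude = 2e-3)
      )
      main <- sim(s, 1, artifacts = arts)
      rep_trace <- sim(s, 2)
      list(entry(s, main, truth = list(artifact_steps = c(2L, 5L)),
                 repeat_trace = rep_trace))
    }
  )
  structure(list(scenario = scenario, seed = seed, protocol = protocol,
                 chip = chip, config = config, calibration = calibration,
                 entries = entries),
            class = "crir_bundle")
}

#' Run the analysis pipeline on a session bundle
#'
#' Composes analysis of every trace in a bundle: pulse detection, curve
#' assembly (merging repeat traces for artifacted steps), sigmoid fitting,
#' and then either settings advice (curve-family scenarios) or fault
#' triage (gaze-condition scenarios). All results are deterministic given
#' the bundle's seed; when `output_dir` is given, results are additionally
#' written as JSON (with embedded schema version).
#'
#' @param bundle A `crir_bundle` from [generate_fixture()] (or assembled by
#'   hand with the same structure).
#' @param output_dir Optional directory for JSON outputs.
#' @param ambient Ambient luminance interval for the advisor, cd/m2.
#' @param dark_luminance Dark reference for the advisor, cd/m2.
#' @return A list with `log` (a tibble: stage, entry, message), `fits`
#'   (for family scenarios) or `amplitudes`, and `recommendation` or
#'   `diagnosis`.
#' @export
run_pipeline <- function(bundle, output_dir = NULL, ambient = c(1, 100),
                         dark_luminance = 0.1) {
  if (!inherits(bundle, "crir_bundle") || length(bundle$entries) == 0) {
    stop("empty or invalid bundle", call. = FALSE)
  }
  fault <- bundle$scenario %in% c("broken_wire", "loose_connection")
  log <- list()
  note <- function(stage, entry, msg) {
    log[[length(log) + 1]] <<- tibble::tibble(stage = stage, entry = entry,
                                              message = msg)
  }
  if (fault) {
    amplitudes <- purrr::map_dfr(seq_along(bundle$entries), function(i) {
      e <- bundle$entries[[i]]
      m <- detect_pulses(e$trace)
      note("detect", i, sprintf("%d pulses, condition %s rep %d",
                                nrow(m), e$condition, e$rep))
      tibble::tibble(condition = e$condition, rep = e$rep,
                     amplitude = m$amplitude)
    })
    diagnosis <- diagnose_device(amplitudes,
                                 noise_rms = bundle$config$noise_rms)
    note("diagnose", NA_integer_, diagnosis$status)
    result <- list(log = dplyr::bind_rows(log), amplitudes = amplitudes,
                   diagnosis = diagnosis)
    if (!is.null(output_dir)) {
      dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(
        list(schema_version = SCHEMA_VERSION, scenario = bundle$scenario,
             seed = bundle$seed, status = diagnosis$status,
             threshold = diagnosis$threshold, evidence = diagnosis$evidence),
        file.path(output_dir, "diagnosis.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    return(result)
  }

  fits <- purrr::map(seq_along(bundle$entries), function(i) {
    e <- bundle$entries[[i]]
    m <- detect_pulses(e$trace)
    rm_ <- if (!is.null(e$repeat_trace)) detect_pulses(e$repeat_trace)
    curve <- assemble_curve(m, bundle$protocol, e$settings,
                            repeat_measurements = rm_)
    fit <- fit_sigmoid(curve)
    note("fit", i, sprintf("settings %s: %s", format(e$settings),
                           if (fit$converged) "converged" else "failed"))
    fit
  })
  family <- as_crir_family(fits)
  recommendation <- recommend_settings(family, ambient, dark_luminance)
  note("advise", NA_integer_,
       if (is.null(recommendation$chosen)) "no qualifying settings"
       else format(recommendation$chosen))
  result <- list(log = dplyr::bind_rows(log), fits = fits, family = family,
                 recommendation = recommendation)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(schema_version = SCHEMA_VERSION, scenario = bundle$scenario,
           seed = bundle$seed, fits = purrr::map(fits, fit_to_list)),
      file.path(output_dir, "fits.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(
      list(schema_version = SCHEMA_VERSION, scenario = bundle$scenario,
           seed = bundle$seed, ambient = ambient,
           chosen = if (is.null(recommendation$chosen)) NULL
                    else unclass(recommendation$chosen),
           qualifying = recommendation$qualifying,
           rejected = recommendation$rejected),
      file.path(output_dir, "recommendation.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
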