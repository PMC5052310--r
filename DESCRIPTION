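Package: crir
Title: Simulation and In Vivo Analysis of Corneally Recorded Subretinal Implant Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and analysis of corneally recorded implant
    responses (CRIRs) from subretinal visual prostheses. Models the implant's
    sigmoidal luminance-to-voltage transfer characteristic and the mapping
    from handheld-unit knob settings (sensitivity V_gl, gain V_bias) to curve
    parameters; simulates the full electroretinographic recording chain
    (anodic chip pulses, capacitive electrode-tissue coupling, amplifier,
    ADC quantization, cascaded digital Bessel band-pass filtering, noise and
    artifacts); and recovers the in vivo transfer characteristic from
    recorded traces by stimulus-locked pulse detection, amplitude extraction,
    artifact rejection, four-parameter logistic fitting and segmentation into
    subthreshold, slope and saturation regions. Includes a settings advisor
    implementing lowest-necessary-output selection rules and a rule-based
    device fault triage (absent output, gaze-dependent intermittent signal).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
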