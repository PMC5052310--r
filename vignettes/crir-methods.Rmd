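---
title: "Corneally recorded implant responses: model, signal chain and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corneally recorded implant responses: model, signal chain and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crir)
```

## The problem

Subretinal visual prostheses of the Alpha IMS type replace lost
photoreceptor function with a microphotodiode array (MPDA): 1500
photodiode–amplifier–electrode pixels on a 3 mm chip, each emitting one
rectangular anodic voltage pulse per frame (1 ms wide, 5 frames per second
by default) whose amplitude follows the luminance falling on that pixel.
The pixel's luminance-to-voltage relation — the *transfer characteristic* —
is sigmoidal in log luminance. Two knobs on the patient's handheld unit
reshape it: `v_gl` (amplifier sensitivity) slides the curve along the
log-luminance axis, and `v_bias` (gain) scales its maximal output. Only
luminances falling on the steep *slope* region of the sigmoid are converted
into graded output; below it (*subthreshold*) nothing is perceived, above
it (*saturation*) bright lights are no longer told apart.

After implantation the curve cannot be probed directly, but each stimulation
pulse leaks a measurable voltage to the cornea. Recording these corneally
recorded implant responses (CRIRs) with a standard full-field ERG setup
while stepping a Ganzfeld stimulator through increasing flash luminances
recovers the transfer characteristic in vivo. This package implements both
directions: a forward simulator of the implant plus the whole ERG recording
chain, and the analysis pipeline that turns recorded traces back into fitted
curves, region segmentations, settings recommendations and device fault
triage.

## The transfer-curve model

The curve is a four-parameter base-10 logistic in $x = \log_{10} L$:

$$V(L) = v_\min + \frac{v_\max - v_\min}{1 + 10^{-s\,(x - x_\mathrm{mid})}}$$

with dark output $v_\min$ (V), saturation output $v_\max$ (V), midpoint
$x_\mathrm{mid}$ (log10 cd/m²) and dimensionless slope $s$ (per log10
unit). The 10–90% crossings of this curve delimit the slope region; their
log-distance, the *dynamic range*, is $2\log_{10}(9)/s$, so the default
$s = \log_{10}(81)/2 \approx 0.954$ makes it exactly 2.0 log units — the
span the device family is known to cover.

### Knob calibration

The true knob-voltage mapping of the device is proprietary and is in
practice individualized per patient, so the package treats it as an
explicit, swappable calibration object (`crir_calibration()`) with these
defaults:

* **Midpoint:** $x_\mathrm{mid} = -1 + 4.5\,(v_{gl}/99)$, a strictly
  increasing affine map. The knob range then sweeps the curve across the
  4–5 log units of luminance over which CRIRs are measurable, and
  curves at different `v_gl` are exact horizontal translations of one
  another.
* **Gain:** the output swing $v_\max - v_\min$ follows a Gaussian-shaped
  factor $g(v_{bias}) = \exp(-\tfrac12((v_{bias}-65)/25)^2)$. The peak at
  65 sits inside the 55–75 window where maximal in vivo output is
  typically observed; in vitro the output would grow monotonically with
  `v_bias`, but in vivo both higher and lower values reduce it, and the
  unimodal map reproduces that. The peak swing is 2.0 V on the chip side.
* **Dark output:** above `v_bias = 70`, $v_\min$ rises quadratically to
  30% of the peak swing at 99. This reproduces the clinically undesirable
  curves that stimulate continuously in the dark, so the advisor's
  elevated-dark-output rule has something real to reject. The magnitude is
  a calibration constant, not a measured device property.
* **Slope:** $s = 0.954\,(0.3 + 0.7\,g)$. Gain changes are described as
  changing both the saturation level and the slope; coupling the
  dimensionless slope affinely to the gain factor realizes that while the
  floor of 0.3 keeps low-gain curves steep enough to saturate within the
  4-log-unit protocol. (Strict proportionality $s \propto g$ would make
  low-gain curves flatter than the whole measurable range, hence
  unfittable, which matches no reported observation.)
* **Corneal attenuation:** derived as
  $35\,\mathrm{mV} / \max(\text{chip } v_\max)$ so that the largest
  corneal response over the entire knob grid equals 35 mV — the published
  ceiling that recording equipment must accommodate. With amplifier gain
  10 this is 0.35 V, safely inside the ±0.5 V input range.

## The stimulus protocol

`build_protocol()` defaults to the clinical series: nine 350 ms full-field
flashes from 0.1 to 1000 cd/m² in 0.5 log steps. The inter-step interval
(2 s) and the 0.5 s lead-in are not part of the published series; they were
chosen once so the 0.312 Hz high-pass settles between steps and the first
pulse has a baseline window. The chip free-runs at its working frequency
rather than being stimulus-locked, so the number of pulses per flash is
$\lceil (d - \phi) f \rceil$ for flash duration $d$ and phase $\phi$ — one
or two per 350 ms flash at 5 Hz, exactly as observed clinically. Phase 0 is
the default; a seeded random phase is available since the real chip's frame
clock is not synchronized to the stimulator.

## The signal chain

`simulate_recording()` composes five stages:

1. **Chip pulses** — rectangular, anodic, `pulse_duration` wide (1 ms),
   amplitude $V(L)$ at each expected pulse time.
2. **Electrode–tissue coupling** — the capacitive interface turns each
   rectangular pulse into a charge-balanced biphasic corneal deflection,
   modeled as a single-pole high-pass with $\tau = 0.5$ ms. $\tau$ is a
   declared simplification (the real chip-to-cornea transfer depends on
   electrode capacitance, tissue resistance and return geometry); 0.5 ms
   makes the within-pulse rise visible at 1 ms width. The corneal peak is
   attenuation × pulse amplitude.
3. **Noise and artifacts** — seeded Gaussian noise, 20 µV RMS referred to
   the amplifier input by default: small enough that the dimmest default
   steps stay above the detection threshold, large enough that detection is
   not trivial. Injected artifacts (blink transients, dropouts) carry
   ground-truth labels in the trace metadata. Noise enters here — at the
   amplifier input, before digitization — because that is where it arises
   physically; the filtered trace therefore carries band-limited noise.
4. **Amplifier and ADC** — gain 10, hard clip at ±0.5 V, 16-bit uniform
   quantization (half-LSB accurate), a 12-bit DC-offset register (default
   0), values referred back to the input. Rail samples are flagged.
5. **Digital Bessel band-pass** — a cascade of second-order Bessel
   high-pass (−3 dB at 0.312 Hz) and low-pass (300 Hz) sections. Each
   section starts from the closed-form 2nd-order Bessel prototype (poles of
   $s^2 + 3s + 3$, rescaled so its −3 dB point sits at 1 rad/s), is scaled
   to the prewarped cutoff $2 f_s \tan(\pi f_c/f_s)$, and is discretized
   with the bilinear transform. Prewarping pins the realized −3 dB points
   at the nominal frequencies (verified to well under 1%). Filtering is
   causal single-pass, as in the online acquisition device, which produces
   the characteristic delay (~0.8 ms to the peak) and broadening of the
   1 ms pulse. "Second-order cascaded" is interpreted as HP(2) × LP(2);
   the device's exact topology is not public.

Below clipping the whole chain is linear, so measured CRIR amplitudes are a
fixed multiple of chip pulse amplitudes and the fitted curve's *shape*
($x_\mathrm{mid}$, slope, dynamic range) is preserved exactly; only the
voltage scale changes.

## The analysis pipeline

* **Detection** (`detect_pulses()`): one ±20 ms search window per expected
  pulse, a 50 ms pre-pulse baseline window; both chosen relative to the
  200 ms pulse spacing so windows never overlap. Missing responses are
  flagged `low_snr` (threshold 5× noise RMS) rather than dropped — a small
  amplitude at a dim flash is a real subthreshold response.
* **Amplitude** (`measure_amplitude()`): signed extremum of the dominant
  first lobe minus the median pre-pulse baseline. Clinically, amplitudes
  were read off the screen by the examiner without a published convention;
  baseline-to-peak is the default here and peak-to-peak is available as an
  option.
* **Assembly** (`assemble_curve()`): artifact- or clip-flagged pulses are
  excluded; a step whose pulses are all flagged is marked for repetition
  and merged from a repeat trace when supplied, mirroring the clinical
  repeat-the-step rule. Remaining amplitudes are averaged per step
  (arithmetic mean); a step is usable with ≥ 1 unflagged pulse, a curve
  fittable with ≥ 3 usable steps.
* **Fitting** (`fit_sigmoid()`): Levenberg–Marquardt least squares
  (`minpack.lm::nlsLM`) of the four-parameter logistic, bounded so the
  swing and slope stay nonnegative. Initialization: $v_\min$/$v_\max$ from
  the amplitude extremes, $x_\mathrm{mid}$ from the interpolated
  half-range crossing, slope from the endpoint secant scaled by the
  logistic's peak-derivative factor. Restarts use a fixed multiplicative
  jitter grid on slope and midpoint rather than random draws, so fits are
  bit-reproducible regardless of RNG state; the lowest-RSS converged
  start wins. Flat curves (swing < 2 µV) are declared degenerate; curves
  where no start converges are returned with `converged = FALSE` and a
  note — never an exception.
* **Segmentation**: regions follow the fitted 10%/90% crossings ("steep
  part" is not quantified in the clinical literature; 10–90 is the
  conventional choice). The bounds themselves belong to the slope region
  (closed interval). A luminance pair is resolvable iff both members
  classify as slope.

## The advisor and fault triage

`recommend_settings()` encodes the lowest-necessary-output rules: qualify
curves whose slope region fully contains the user-supplied ambient
luminance interval; reject curves whose fitted output at the dark reference
exceeds 10% of the family-wide maximum (the threshold is a declared
operationalization — clinical reports show example curves but no number);
among the rest choose minimal $v_\max$, breaking ties by lower dark output
and then lower `v_bias` (continuous criteria are compared at 6 significant
digits so fitting noise cannot decide a tie). The ambient interval is a
user input because the appropriate range depends on the patient's
environment.

`diagnose_device()` orders its rules exactly as documented: no detectable
pulse in any gaze direction → `device_output_absent` (damaged cable);
detectable in some directions only, or intermittent across repeats within a
direction → `gaze_dependent_intermittent` (loose connection); otherwise
`device_functional`, with a note that a persisting perception problem then
points to a biological cause outside the device test's scope. "Detectable"
means ≥ 5× noise RMS; "intermittent" means presence varies across repeats
within one condition — the clinical description ("non-regular signal") is
not quantified, so this operationalization is declared here.

## What the synthetic data does and does not emulate

`generate_fixture()` produces labeled sessions for seven scenarios (clean
families, knob sweeps, elevated dark output, broken wire, loose connection,
artifact-heavy). It emulates: the luminance series, free-running pulse
timing, biphasic pulse morphology, amplifier/ADC limits, causal band-pass
filtering, input-referred Gaussian noise, and labeled blink/dropout
artifacts. It does **not** emulate physiological ERG components (end-stage
retinitis pigmentosa patients contribute essentially none), 50 Hz mains
interference, electrode impedance variation, pixel-to-pixel inhomogeneity
(all 1500 pixels are lumped under full-field illumination), or spectral
effects of the stimulator LEDs. Passing tests therefore demonstrate
correctness of the method under this generative model, not robustness to
every clinical nuisance; real recordings with large physiological or mains
contamination would need additional preprocessing.

## Numerical choices and problem sizes

Example:

```{r}
trace <- simulate_recording()   # defaults: 20/65, 9 steps, 20 uV noise
curve <- assemble_curve(detect_pulses(trace), settings = knob_settings())
fit <- fit_sigmoid(curve)
fit
glance(fit)
```

Degenerate inputs are routed to flags (`degenerate`, `converged`,
`fittable`) rather than errors throughout, because a clinical session must
keep going when one curve is flat — that flatness is itself diagnostic.
Validation exercises use full-length default sessions (9 steps, ~21 s at
5 kHz); parameter-recovery checks use 50 seeded noisy replicates, and fault
triage is validated over 50 seeded sessions per scenario. Knob-grid bounds
are verified in closed form over the full 100 × 100 grid (the corneal peak
is attenuation × $v_\max$, so simulation is only needed for spot checks).

## Known limitations

* All knob maps are calibrations, not measured device properties; the
  per-patient variability of the real mapping is represented only through
  the swappable calibration object.
* The single-pole coupling model reproduces first-lobe amplitude and
  charge balance but not every detail of recorded pulse shapes, which
  depend on multiple unmodeled tissue factors.
* CRIR amplitude is a surrogate for device output; the link to perceptual
  thresholds varies between and within patients and is deliberately out of
  scope.
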