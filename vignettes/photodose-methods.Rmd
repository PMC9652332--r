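---
title: "Models and methods behind photodose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind photodose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photodose)
```

photodose plans and simulates light treatments for multiwell-plate
photodynamic therapy (PDT) experiments delivered by a PWM-driven LED array.
This vignette is the package's account of the science: the models it
implements, the assumptions behind them, the tunable parameters and their
defaults, and what the synthetic-data tests do and do not demonstrate.

## Spectral overlap efficiency and effective light dose

A photosensitizer absorbs a broadband LED's output less efficiently per unit
fluence than a laser line parked on its absorption peak. photodose
quantifies this with the absorption-weighted mean of the source spectrum,
normalized to the absorption at the reference laser wavelength:

$$\epsilon \;=\; \frac{\int S(\lambda)\,A(\lambda)\,d\lambda}
                      {\int S(\lambda)\,d\lambda\;\cdot\;A(\lambda_\mathrm{ref})}$$

with the *effective light dose* defined as $\epsilon$ times the delivered
fluence. The analogous factor built from the power meter's responsivity
$R(\lambda)$ converts a broadband meter reading into true irradiance; it is
applied to the **reading**, before any fluence is accumulated, and the order
of operations is recorded in the result object. Both integrals use the
trapezoid rule on the union grid of the inputs — exact for the
piecewise-linear sampled data, and consistent with the linear interpolation
used everywhere else in the package. Spectra are zero outside their sampled
support: emission and absorption bands are physically bounded, so
extrapolation would manufacture signal.

Two genuinely open choices are resolved as follows:

* **Energy- vs photon-weighted overlap.** The defining integral can weight
  by energy (as above) or by photon number (an extra factor of $\lambda$).
  The energy weighting is the default because irradiance and fluence are
  energy quantities; `weighting = "photon"` selects the variant. Over a
  ~30 nm band near 690 nm the two differ by well under 1%.
* **The laser as a delta line.** The reference laser is treated as an exact
  line at $\lambda_\mathrm{ref}$ rather than a narrow measured spectrum,
  because the normalization is defined against $A(\lambda_\mathrm{ref})$.

For peak-width reporting, `fwhm_interval()` finds the outermost half-maximum
crossings with linear interpolation. LED spectra carry measurement ripple,
so secondary maxima below 5% of the peak are ignored (configurable); bigger
secondary peaks indicate a genuinely multimodal spectrum and raise an error
rather than returning a misleading width.

```{r}
fx <- generate_fixtures(1)
fwhm_interval(fx$led)
spectral_efficiency(fx$led, fx$absorber, 690, fx$detector)
```

The synthetic fixtures emulate the shapes that matter — a Gaussian LED band
with half-maximum crossings at 676 and 702 nm, a 10 nm-wide absorption band
at 690 nm, a near-flat detector — but not the asymmetric tails and vibronic
structure of real measured spectra. A passing overlap test therefore
validates the integration machinery and its limits (delta-source
$\epsilon \to 1$, sub-nanometre shift insensitivity), not any particular
printed efficiency value for a real LED/photosensitizer pair.

## PWM irradiance control

The LED drive is a square wave synthesized sample-by-sample on a DAQ analog
output: a 250 Hz carrier from a 5 kHz sample clock gives 20 samples per
period and hence 20 representable nonzero duty cycles in 5% steps. Average
irradiance is linear in duty because the switching transistors commute in
under 100 ns — negligible against a 4 ms period. The calibration is a
least-squares line through measured (duty, irradiance) points with free
intercept; a lookup-table mode is provided where high-duty sensor
saturation makes the line a poor summary. `duty_for_irradiance()` picks the
representable duty nearest the target and breaks ties toward the **lower**
duty: under-dosing is the safer failure mode in a cytotoxicity assay.

Exposure times are *not* re-quantized to whole PWM periods by default; the
worst-case sub-period dose error (at most one period's worth of fluence,
i.e. 4 ms × irradiance) is reported per visit in the plan, and a
`quantize_periods` switch selects the rounding behaviour instead.

## Plate geometry, layouts and motion

Plate geometry follows the ANSI/SLAS footprint (9.0 mm pitch for 96-well,
19.3 mm for 24-well); the source instrument description does not state
plate dimensions, so these standards are design choices. Wells use "A1"
names only at parse/serialize boundaries; internally everything is 0-based
(row, col).

`canonical_layout_96()` builds the standard dose-response layout: 16 groups
of six wells (2×3 footprints) — two treatment series over the
2, 4, 6, 8, 10, 12 J/cm² ladder plus the four controls (DNL, LND, NDNL,
MO). The two series are staggered so that no two groups sharing a dose sit
in edge-adjacent footprints: if the stage is misaligned by one footprint,
the resulting dose pattern is visibly wrong instead of silently swapping
replicates. `validate_layout(staggered = TRUE)` checks this property for
user-supplied layouts.

Motion is two independent screw axes at a configurable step size, default
25 µm/step following the builders' stated precision. (Note their own
figures — 5 mm pitch at 400 steps/rotation — work out to 12.5 µm; the
discrepancy is why this is a config value.) Steps are rounded to the nearest
integer, so the residual placement error is at most half a step (12.5 µm),
an order of magnitude below the repeatability a plate-positioning camera
would resolve.

`plan_experiment()` ties these together: every group with a nonzero dose is
visited once in row-major centroid order (configurable), the LND control is
always illuminated at the maximum treatment dose, and dark controls are
carried as zero-illumination rows so the plan documents the whole plate.

## Sensors and the electrical budget

Both on-board sensors are read through resistive dividers off the 12 V
supply (5 kΩ fixed for the thermistor, 10 kΩ for the phototransistor). The
divider orientation is not stated in the source design; photodose defaults
to sensor-on-top, output across the fixed resistor, so the output voltage
*rises* with temperature and with light — the intuitive polarity — and the
orientation is a constructor flag. The thermistor follows the NTC beta
model $R(T) = R_0 e^{\beta(1/T - 1/T_0)}$ with config-exposed constants
(defaults: 10 kΩ at 25 °C, β = 3950 K, a ubiquitous bead); readout
inversion is closed-form, and round-trips to better than $10^{-9}$ °C. The
phototransistor uses a linear fit with the maximum absolute residual
reported, documenting how far mild saturation pulls the device from
linearity.

The electrical budget is elementary but worth automating: 5 parallel
branches × 600 mA = 3 A total; a 4 mm × 0.07 mm copper lead has the
cross-section of AWG 23 wire (nearest-by-area, ties to the thinner gauge);
the lead drop is $I\rho L/(wh)$ with ρ = 1.68×10⁻⁸ Ω·m, and a 0.04 V drop
is ~0.3% of the 12 V series branch. Lead length is an input — it depends on
the board run, and is not part of any standard.

## The irradiance field model

Each of the 25 emitters (5×5 grid spanning 33 mm edge-to-edge, so
8.25 mm pitch — an assumption, as only the overall extent is documented)
radiates with a radially symmetric angular profile, Gaussian in the polar
angle with half intensity at 12°. The datasheet phrase "light within 24
degrees" is read as a full cone, i.e. a 12° half-angle; this is
config-exposed since the reading is ambiguous. Irradiance at the sample
plane superposes per-emitter intensity × cos θ / r² contributions. Because
the solid-angle integral over the plane is exact, plane-integrated power
conserves emitted power, which the tests verify to 2% on a finite grid.

The Fresnel lens and diffuser are **not** ray-traced — no prescription is
available. Their effect is absorbed into the effective angular profile plus
a scalar transmission, which `calibrate_transmission()` pins so the peak
field matches a measured maximum (400 mW/cm² at full duty). Consequently
the model supports *relative* statements — uniformity orderings, masking,
per-well averaging — not absolute replication of measured well powers, and
the printed uniformity figures (4.01% LED vs 10.2% laser) are deliberately
not targets. The laser comparator is a circular Gaussian beam with a
config-exposed waist (default 25.4 mm; no beam radius is published), and
the package asserts only the ordering: the LED array illuminates a 3×3
group more evenly than the Gaussian beam.

One property worth flagging: centre-vs-corner uniformity is *not* monotone
in the emitter half-angle. Narrow beams leave per-emitter ripple across the
group; wide beams dome the superposed field toward the array centre. On the
default geometry the optimum sits near a 10° half-angle, and the property
test asserts this interior optimum rather than a monotone trend.

## The thermal model

Sample heating is a first-order lumped model: Newtonian relaxation toward
an irradiance-dependent steady state
$T_\infty = T_\mathrm{env} + g(I)\,I$. The gain is a per-irradiance table
with linear interpolation because the anchoring observations — rises of
15.6 °C at 100 mW/cm² and 28.8 °C at 200 mW/cm² from a 20.2 °C start — are
not proportional to irradiance, so a single linear gain cannot reproduce
both. With these anchors the model reproduces the 35.8 °C and 49.0 °C
steady states exactly by construction.

The time constant τ is not directly measured anywhere. The default
τ = 890 s places the 37 °C crossing of the 200 mW/cm² curve at ~13 min,
consistent with the observed heating behaviour; all τ-dependent outputs
(crossing times, end-of-exposure temperatures) should be read as
model-relative. `time_to_threshold()` is closed-form,
$\tau \ln\!\frac{T_\infty - T_\mathrm{env}}{T_\infty - T_\mathrm{thresh}}$,
and is cross-checked against numeric ODE integration in the tests.

`max_safe_plan()` offers two safety horizons. The default, `"steady"`,
requires $T_\infty < T_\mathrm{thresh}$ at the chosen irradiance — a
τ-independent, conservative rule encoding the practical guidance that
raising irradiance cannot shorten an experiment that would overheat, and
the reason 100 mW/cm² is the working ceiling for a 37 °C limit.
`"exposure"` checks only the end-of-exposure temperature; it admits short
hot exposures but leans on the weakly constrained τ, which is why it is
not the default.

## Dose-response analysis

Raw luminescence normalizes against the plate's own controls — NDNL mean =
100%, MO mean = 0% — making the viability scale, and everything downstream,
exactly invariant to affine rescaling of the reader output. The
dose-response model is the variable-slope four-parameter logistic
$$v(d) = \mathrm{bottom} + \frac{\mathrm{top}-\mathrm{bottom}}
                                {1 + (d/EC_{50})^{h}},$$
fitted by Levenberg–Marquardt least squares with EC50 on a log₁₀ scale
(doses span decades; the log parameterization keeps EC50 positive and its
standard error meaningful, transformed back by the delta method). Starting
values are top/bottom from the extreme-dose means, EC50 from the
interpolated 50% crossing of group means, hill = 1. Top and bottom are
free by default, matching the named Prism model's unconstrained variant;
whether the original analyses pinned them at 100/0 is unstated, so both
are available as constraint arguments. Degenerate inputs — fewer than four
distinct doses, a flat response — error out with named conditions rather
than returning a nonsense fit. `effective_ec50()` multiplies by $\epsilon$
to put LED-array EC50s on the laser dose scale; laser fits use
$\epsilon = 1$.

```{r}
tbl <- generate_viability_table(seed = 1)
fit <- fit_dose_response(tbl)
tidy(fit)
```

The generator's defaults are the study conditions of a standard experiment:
the 2–12 J/cm² ladder, six replicates per group, 5% CV multiplicative
noise, and a mid-range true EC50 of 6 J/cm² (top 100, bottom 0, hill 2).
Parameter-recovery results under these conditions say the estimator is
consistent and well-conditioned for this design; they do not reproduce any
cell-line-specific EC50, which requires the biological data. Note the
replicate spread of simulated viability peaks where the dose-response curve
is steepest — dose jitter maps to response spread through $|dv/dd|$ — which
is also the variance pattern seen in real multiwell dose-response data.

## The virtual rig

`run_plan()` executes a treatment plan against software hardware: a virtual
clock (no wall-clock sleeps, so full plates simulate in milliseconds),
stepper axes with integer-step landing positions and travel limits, seeded
Gaussian sensor noise (0.1 °C thermistor, 1 mW photosensor equivalents),
and per-well fluence accounting — achieved irradiance × on-time for each
well in the visited group's aperture, with no light during motion. The
accounting identity (total fluence = Σ irradiance × time × wells) holds to
machine precision, and identical seeds give bitwise-identical logs. A
thermal interlock projects each exposure with the lumped model and refuses
plans that would cross the configured ceiling unless explicitly overridden.
Inter-visit settling dwell defaults to 0 s (undocumented in the source
design) and is config-exposed.

Problem sizes used throughout the test suite — full 96-well plans, 0.5–1 mm
field grids, 200-seed Monte-Carlo recovery runs, 60-point thermal curves —
were chosen as the smallest sizes at which each property is
unambiguous; they keep the whole suite under a minute on a laptop-class
core.

## Known limitations

* The field model's absolute scale is a calibration, not a prediction; use
  a measured peak irradiance.
* No radiative transfer in media or well plastic, no photobleaching or
  singlet-oxygen kinetics: fluence is the dose metric throughout.
* The thermal model is lumped; it cannot resolve spatial gradients across
  the plate or distinguish plate-wall from media absorption.
* The 4PL fitter assumes a monotone response; biphasic dose-response data
  needs a different model.
* Motion simulation omits backlash, homing and electrical step timing —
  adequate for dose bookkeeping, not for mechanical design.
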