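---
title: "Models and methods behind plateflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind plateflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plateflow)
```

`plateflow` is a pure-software model of a robotic platform that delivers
fluids serially from a multiwell plate into a microfluidic device through a
single inlet tube, raised and lowered by a servo while the plate moves
underneath. This vignette documents the models the package implements, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the design decisions taken where the system description left
the choice open.

## The transition choreography

A well-to-well transfer must never draw an air bubble into the open tube
tip. The compiled event order is therefore fixed: close the outlet valve
(stopping flow), open the backpressure valve (an elevated reservoir whose
hydrostatic head `rho * g * h` balances the capillary pressure at the tip),
raise the tube, move the plate, lower the tube into the next well, close
the backpressure valve, reopen the outlet. `validate_timeline()` checks the
machine-level safety invariant that the outlet valve is never open while
the servo is raised.

The seven phase durations are configurable via `timing_profile()`. The
system description gives only the total ("under 2 s" for an adjacent
move); the default split 0.2/0.1/0.5/0.35/0.5/0.1/0.2 s totals 1.95 s for
a one-well move, deliberately just inside that bound, with the plate-move
phase scaling with Chebyshev well distance (the x-y stage moves both axes
at once). Strictly sequential valve switching is enforced; if the real
hardware overlaps valve transitions by a few milliseconds, the compiled
timeline is a conservative superset of the safe behaviour.

## Breakthrough of a fluid switch

After a switch the new fluid must flush the old one from the inlet tube
(22 cm, 250 µm ID, 10.8 µL by `pi * a^2 * L`). The front disperses by
Taylor–Aris dispersion: at mean velocity `U = Q / (pi a^2)` the effective
axial coefficient is

    K = D + a^2 U^2 / (48 D)

and the exit concentration of the new fluid follows

    c(t) = 1/2 * erfc( (L - U t) / (2 sqrt(K t)) ).

`c` is exactly 0.5 after one tube volume of flow and reaches 99.9% at
about 4.5 tube volumes at the defaults (2 µL/s, fluorescein diffusivity
`D = 4.25e-10` m²/s, a literature value — the solute is configurable),
consistent with the working rule that ~5 tube volumes (~27--30 s) complete
a switch. Two caveats are built into the API rather than hidden:

* **Regime validity.** Taylor's closed form assumes the radial diffusion
  time `a^2/D` is short against the transit time `L/U`. At the default
  operating point the ratio is ~6.8, i.e. the regime is marginal, so the
  closed form is an approximation of the true front.
  `dispersion_regime()` reports the ratio and `breakthrough(warn_regime =
  TRUE)` warns. The qualitative behaviour (sigmoid centred on one tube
  volume, completeness within a few volumes) is what the package relies
  on.
* **Carryover is not the dispersion tail.** The measured residual
  (~0.32% at a 30 s fill delay) is far above the ideal erfc tail, likely
  due to surface adsorption or dead volume; the package therefore models
  carryover as a separate calibrated residual fraction `f` per switch
  (default 0.0032, switch-to-switch SD 4.7e-4) with a geometric per-wash
  reduction `r` (default 0.1, "an order of magnitude" per wash), rather
  than deriving it from the physics. `carryover_after_washes()` gives
  `100 * f * r^washes` percent.

In the plug-flow limit (`dispersion = FALSE`, `D -> 0`) the breakthrough
is a step at exactly one tube volume, which the tests use as an oracle for
the dispersion term.

## The carryover assay and its layout

The assay alternates fluorescein (5 µg/mL) and water across a full
96-well plate scanned in a snake pattern. The protocol this assay
reproduces counts 48 dye-to-water switches — which requires the dye to
come first along the scan — yet also designates well A1 (water, in a
buffer-first layout) as the camera baseline; both conventions cannot hold
in one alternating layout. The package resolves this in favour of the
switch count, which is the scientific quantity: `carryover_assay_map()` puts dye first so that all 48
water wells follow a dye well, and the camera baseline comes from a
pre-scan dark recording emitted by the generator (`carryover_table()`
accepts a numeric baseline or any well reference, so the buffer-first
convention remains available). The dark baseline is averaged over all its
frames rather than the first/middle/last convention used for the (motion-
limited) well videos, because a shared baseline error shifts all 48 ratios
coherently and would dominate the error budget of the mean.

Carryover per water well is `100 * (I_water - I_0) / (I_dye - I_0)`; the
table reports the per-well percents and their mean ± SD.

The snake is assumed to start left-to-right on row A; the alternative
orientation is available via `traversal_order(first_direction = "rtl")`
since the original description does not pin it down.

## Protocol compilation

`compile_protocol()` turns a plate map plus a list of `protocol_step()`s
into a timed event stream. Times are seconds (floating point) relative to
protocol start. Per step: transition, fill delay (tube flush under flow,
default 30 s ≈ 5 tube volumes), optional stimulus pulses and camera
acquisitions scheduled relative to fill-delay completion, then the
exposure itself. Steps of ≥ 30 min default to paused flow (both valves
closed) — without pausing, a 30 min step would draw 3.6 mL from a 2 mL
well, so the volume-budget validator (`flowrate * flowing time` against
the loaded volume) would reject it. Wash steps are ordinary steps
targeting wash wells; no special event type exists.

The built-in ten-step staining protocol (PBS / 10 min PFA / PBS / 10 min
Triton X-100 / PBS / 30 min BSA / 30 min phalloidin / PBS / 3 min Hoechst
/ PBS) sums to exactly 85.5 min of fluid exposure; the first step has no
fill delay because the tube is pre-filled with the first solution by a
backpressure-driven reverse fill before the run, giving a ~90.3 min total
timeline consistent with a 90-frame, 1 frame/min monitoring recording.

## Command codec

The serial grammar is `[row letter][column][+ or -]` per move (raise,
move, then stay raised `+` or lower `-`), `0` for home, `;` between
segments. Parsing is case-insensitive and accepts multi-digit columns up
to 24 (384-well); encoding is canonical uppercase. `parse_commands()` is
the exact inverse of `encode_commands()` on valid token tables, enforced
by a property test over random tokens.

## Synthetic data: what is and is not emulated

The generators produce the statistical structure the pipelines need, not
realistic images of worms or cells:

* **Carryover scans** (`gen_carryover_scan()`): per-well frame series with
  Gaussian read noise (default SD 0.5 a.u. on a 100/1100 a.u.
  baseline/dye scale — small because the readout is a 25×25-pixel ROI
  average) and per-switch residuals `Normal(f, f_sd)` truncated at zero.
  An optional image path (`scan_to_stack()`) renders small frames with a
  bright ROI block for end-to-end ROI-extraction tests.
* **Dose–response traces** (`gen_dose_response()`): raw fluorescence
  `F0 (1 + response + noise)` where the response is a unit-peak
  difference-of-exponentials kernel (rise 1 s, decay 5 s — trace shapes
  are not pinned down by the protocol this emulates, so these are
  calibration choices) scaled by `r_max * c^h / (c^h + EC50^h)` and a
  per-pulse adaptation factor. Defaults: AWA EC50 1.15 µM, Hill 1.5, no
  adaptation; ASH EC50 1.15 mM, Hill 3, adaptation 0.5 per pulse (the
  EC50s are stated values; Hill slopes and the adaptation rate are
  calibration stand-ins, so validation rests on parameter *recovery*, not
  point-by-point curve match). Animal-to-animal variability is a
  multiplicative lognormal factor (SD 0.2); trace noise is additive
  Gaussian, SD 0.05 ΔF/F0. Both are package choices, typical of
  wide-field GCaMP imaging. Cross-neuron `coupling` (ASH
  activity suppressing the AWA peak) is off by default — it is an optional
  emulation of the observed negative correlation, and enabling it (e.g.
  0.3) distorts the pure Hill curve by design.
* **Screen peaks** (`gen_screen()`): one evoked peak per animal and well,
  `baseline_peak * suppression * animal factor + noise`. The default
  suppression table makes isopropanol, methanol and acetonitrile
  suppressors at both 1% and 5% and ethanol at 5% only; beyond those
  four, the remaining names of the 14-solvent panel are representative
  choices with factor 1.
* **Staining time-course** (`gen_staining_timecourse()`): background, then
  a saturating exponential rise (τ = 5 min) starting 15 min into
  phalloidin exposure, sampled at 1 frame/min for 90 min.

All generators are seed-deterministic, and the core closed-loop property —
noiseless generation followed by the matching analysis recovers the preset
parameters exactly — is tested for `f`, the Hill parameters, and the
suppression structure. Passing these tests shows the pipelines are
internally consistent and correctly calibrated; it does not validate them
against real image stacks, animal movement, photobleaching, or optics.

## Quantification choices

* **ΔF/F0**: `F0` is the mean over the final 2 s before stimulus onset
  (a package convention, stated in the config).
* **Peaks**: maximum of the ΔF/F0 series in `[onset, onset + duration +
  5 s]`. Before the maximum is taken the series is smoothed with a 0.5 s
  boxcar; without smoothing the window maximum reads the extreme of the
  frame noise (~2.5 SD over a 150-sample window) and inflates
  low-concentration peaks enough to bias the fitted EC50 visibly downward.
* **Hill fit**: least squares (Levenberg–Marquardt) with EC50 on the
  log10 scale, initialised at the first concentration whose mean peak
  exceeds half the maximum, Hill 1, bounded to the tested span ± 1 decade.
  Non-convergence or a bound-pinned EC50 is reported in the fit object
  (`converged`, `message`, `ec50_in_span`) — never silently replaced. The
  95% CI comes from the asymptotic SE of log10(EC50). A third-degree
  polynomial in log10 concentration (buffer excluded — zero has no log)
  is carried purely as the display convention; per-concentration
  summaries carry SEM under both conventions (n = animals with pulses
  averaged first, and n = all traces), since both appear in practice.
* **Screen statistics**: per animal, solvent-well peak minus the
  immediately preceding buffer-control peak, tested against zero with a
  one-sample t computed from its definition (`mean * sqrt(n) / sd`),
  two-sided, Bonferroni-corrected at `alpha = 0.001` over `m = 28`
  comparisons (14 solvents × 2 concentrations, configurable). A
  zero-variance difference vector is reported as degenerate rather than
  significant. A one-way repeated-measures F across wells
  (`screen_rm_f()`) is offered as a secondary descriptive report,
  standing in for the GLM repeated-measures route, which the original
  analysis found to give similar results.
* **Staining onset**: first minute at/after phalloidin start exceeding
  the pre-phalloidin background mean by 3 background SDs, reported
  relative to phalloidin exposure start; a flat series yields `NA`. At a
  1/min sampling rate the three 30 s PBS washes can contain no sample;
  their segment means are reported as `NA` with a sample count of zero.

## Numerical and degenerate-input behaviour

`erfc` is computed via `pnorm` (exact relation, no series approximation).
`volumes_to_completeness()` root-finds on the closed form with tolerance
1e-10 and is exactly 1.0 at threshold 0.5 by the symmetry of `erfc`.
Degenerate inputs fail loudly and specifically: zero flowrate, empty
traversal orders, out-of-bounds wells and ROIs, malformed command
segments (named in the error), volume overdraw (naming the well),
non-positive F0, a dye well not above baseline, a missing prior control
(naming the well), a series shorter than its timeline.

## Problem sizes in the test-suite

The suite regenerates everything programmatically: full-size fixtures
where the combinatorics are the point (96-well scans, 18 animals × 8
concentrations × 4 pulses, 20 animals × 57 wells), reduced sizes where
only the statistical property matters (8 animals across 8 seeds for the
EC50-recovery bound; 200 replicate screens of 8 animals for the
type-I-error check, against an expected false-positive count of 0.2).

## Known limitations

* The gap between the ideal dispersion tail and the measured 0.32%
  residual is represented, not explained; the carryover model is
  empirical.
* No two-phase (air slug) dynamics, CFD of the device interior,
  temperature dependence, or photobleaching.
* The backpressure capillary setpoint is a calibration parameter
  (default 200 Pa ≈ 2 cm of water), not computed from contact angles.
* The command codec and scheduler model the control stream, not the
  transport: no serial-port I/O, motor calibration, or limit-switch
  homing.
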