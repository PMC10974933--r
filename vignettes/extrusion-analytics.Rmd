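---
title: "Extrusion analytics for an instrumented semi-solid printhead: models, parameters, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extrusion analytics for an instrumented semi-solid printhead}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssepat)
```

## The problem

Semi-solid extrusion (SSE) 3D printing deposits a drug-loaded gel or
paste from a syringe through a fine nozzle, layer by layer, to build
individual dosage units ("printlets"). Whether a given paste prints at
all — and whether every unit in a batch receives its intended dose — is
governed by the paste's flow behaviour: it must hold shape at rest
(yield stress), flow readily once pushed (shear thinning), and recover
quickly after each deposition stroke. A pressure sensor built into the
plunger turns the printhead itself into the measuring instrument: the
pressure–time trace of a controlled compression is an *extrudability
profile*, and during a production run the same trace, aligned with the
printer's motion, becomes an in-line quality record for every single
dosage unit.

`ssepat` implements that analytics chain end to end, together with a
physics-based generator that stands in for the instrumented hardware so
every stage is testable against known ground truth.

## The extrusion model

The simulator couples two elements:

1. **A lumped compliance.** Paste and syringe together store volume
   elastically: `dP/dt = (Q_in − Q_out) / C`, with `Q_in = v_plunger ×
   A_syringe` and `C` in mm³/kPa.
2. **Herschel–Bulkley capillary discharge.** No outflow below the yield
   pressure `P_y`. Above it, the excess wall stress `(P − P_y) · r /
   (2L)` drives power-law (Rabinowitsch) flow through the nozzle,
   `Q_out = π r³ · n/(3n+1) · (τ_excess/K)^{1/n}`.

The measured channel adds a constant plunger-friction pressure and
Gaussian sensor noise (seeded). Each sample advances by a backward-Euler
step solved with safeguarded Newton iteration (the discharge law is
monotone in `P`, so the step equation has a unique root); the integrator
is unconditionally stable, which matters because the discharge becomes
stiff for thin fluids. For a Newtonian fluid (`n = 1`, `P_y = 0`) the
steady state reduces exactly to the Hagen–Poiseuille pressure drop,
which the test suite uses as an independent closed-form oracle.

Process upsets are first-class: a *clog* shrinks the nozzle radius by a
fraction over a time window; an *air bubble* multiplies the compliance
(and instantaneously divides the stored pressure) over its window.

### Default parameters and why

| Parameter | Default | Rationale |
|---|---|---|
| syringe inner diameter | 19.3 mm | reproduces the 0.010 mm/s plunger speed at a 10 mm/s print speed and 0.61 mm layer height (20 mL Luer-lock syringe) |
| nozzle | 0.61 mm × 25 mm | 20-gauge tapered tip; the length is a geometry default, not a measured value |
| compliance `C` | 0.78 mm³/kPa | makes the pre-yield ramp at 10 mm/s reach yield in ≈110 s, the scale observed for soft pharmaceutical gels |
| yield pressure `P_y` | 400 kPa | mid-range for printable hydrogel pastes |
| consistency `K`, index `n` | 6 Pa·sⁿ, 0.4 | a *yield-dominated* shear-thinning gel: the steady plateau sits ≈8–12 kPa above yield across 10–30 mm/s |
| friction | 8 N | constant sliding force of the plunger seal (≈27 kPa on this syringe) |
| noise | 5 kPa SD | sensor-level white noise |

The yield-dominated regime is a deliberate modelling choice. Under a
quasi-static compliance model, the post-yield pressure rise above `P_y`
is what separates the trace from its pre-yield linear ramp; if that rise
is large (a strongly consistency-dominated paste), the
departure-from-linearity reading of the yield point is intrinsically
biased upward by hundreds of kPa, because outflow grows too gradually to
bend the curve at `P_y` itself. Real instrumented-printhead traces of
printable gels show a sharp knee, which this model reproduces only when
the steady excess stress is small against the yield pressure. The
generator therefore emulates pastes whose plateau hugs the yield point;
what passing recovery tests demonstrate is that the profiling stage is
unbiased *for such pastes*, not that it can read the yield point of an
arbitrary Herschel–Bulkley fluid from a single trace.

## Extrudability profiling

`extract_profile()` reads a compression/hold trace the standard way:

* **Phases** come from the commanded displacement channel (first
  monotone advance = compression; the stationary stretch after it =
  hold).
* **Pre-yield linear region**: the longest expanding window of the
  pressure–displacement curve with `R² ≥ 0.99` (configurable).
* **Yield point**: the first sustained (3-sample) departure of the
  (median-smoothed) pressure from that fit by more than 5 % of the
  predicted value; reported as the local median around the departure
  sample so one noisy reading cannot carry the estimate. The Young
  modulus is re-fit strictly below `(1 − 5 %) ×` yield so the knee does
  not bias the slope.
* **Steady state**: the final 20 % of the compression step;
  **flow cessation**: the final 5 s of the hold.
* **Derived quantities**: shear rate `4Q/(πr³)` with `Q = π·LH²·TPS/4`;
  apparent viscosity = steady stress / shear rate (kPa·s); dynamic
  viscosity from the Poiseuille force balance `F = 128QμLA/(πD⁴)`
  (Pa·s).

Two conventions are switchable because neither is universal: the steady
shear stress may be referred to the nozzle cross-section (default) or to
the capillary wall (`τ = ΔP·r/2L`); and the volumetric flow `Q` has a
legacy "speed × syringe radius" reading available behind
`flow_rate(..., literal = TRUE)` for compatibility with older
spreadsheets (it is dimensionally inconsistent and not used anywhere by
default).

Friction is removed by `baseline_correct()`: an empty-syringe run under
the same protocol, time-interpolated and subtracted.

## Rheometer summaries

The oscillatory stage follows standard gel rheology readings:
`classify_gel()` calls a material gel-like when `G′ > G″` throughout a
frequency sweep with the two moduli parallel on log–log axes (slope
difference ≤ 0.1). `amplitude_summary()` takes the yield stress as the
first departure of `G′` from its low-amplitude plateau (5 % of the
plateau median) and the flow stress as the `G′ = G″` crossover located
by log-linear interpolation between the bracketing sweep points (a
bracket-geometric-mean alternative is a flag). `creep_summary()`
reports, per 60 s on / 60 s off cycle, peak strain, residual strain and
recovered percentage.

The generator behind these uses `G′ = G₀ωᵃ` with a fixed loss ratio for
frequency sweeps; a plateau-then-power-law decay with a slower-decaying
`G″` for amplitude sweeps (the crossover position has a closed form the
tests solve independently); and a Burgers (Maxwell + Kelvin–Voigt)
compliance for creep, whose permanent strain per cycle `σ·t_on/η₁` is
again an analytic oracle.

## Batch design, gcode and motion

`design_batch()` lays out cylindrical printlets (default 60 + 10
priming units at 5 mm/s, 6 mm radius × 2.4 mm height, 0.61 mm layers,
2 perimeter shells, 70 % rectilinear infill) on a square grid and emits
absolute-coordinate RepRap-style gcode with structured
`; PRINTLET <id> BEGIN/END` markers. The stated 1 cm spacing is
implemented as an edge-to-edge gap (22 mm pitch): a centre-to-centre
reading would make 12 mm disks overlap. `randomize_speeds()` reassigns
the requested speed multiset across non-priming blocks as a seeded
uniform permutation, rewriting only the F words of printing moves — so
exactly 20 units per speed, every time, and a byte-level diff confined
to those tokens. `motion_timeline()` applies constant-velocity
kinematics (no acceleration model; the analysis throughout assumes
commanded speed) to give per-sample position, commanded speed and
printlet membership.

## In-line PAT

`segment_by_printlet()` maps each trace sample to the printlet active
at its time. Per unit, `printlet_report()` gives the time-weighted mean
pressure and the trapezoidal area under the force–time curve (force =
pressure × syringe cross-section), with interval weights attributed to
the left sample so segment AUCs and travel AUCs sum *exactly* to the
whole-trace integral.

`detect_anomalies()` flags clogs (pressure excursions up) and air
(down) with a trailing-window robust z-score: residuals against a 20 s
trailing median, scaled by a MAD-based robust SD taken over a longer
(60 s) trailing window that is additionally lagged by the median
window, then smoothed over 2 s and thresholded at 6 robust SDs
sustained for ≥ 1 s. Each design choice closes a specific failure mode:
trailing (not centred) windows keep the baseline anchored to pre-event
signal; the lagged, longer SD window stops an excursion from inflating
its own threshold; the smoothing turns marginal excursions into
sustained runs; and the 20 s/6σ pairing exploits the fact that under a
compliance-buffered printhead *any* pressure ramp is capped at the
charging rate `Q_in/C` — the priming-phase ramp (half the printing-speed
slope) saturates near z ≈ 3.8 while clog ramps at printing speeds reach
z ≥ 7.5. Detection warms up for one SD window plus one median window
(~80 s) at the start of a run.

Consequences worth knowing: a partial occlusion below roughly 50 %
radius reduction at the slowest printing speed stays inside the
detection band and is *not* flagged; and the relaxation after a cleared
clog can register as a short mirror-image "air" event on the same unit.
Severe faults — the 80 % occlusion and the compliance-doubling bubble
used in the test suite — are detected essentially always, on the
correct printlet, with false alarms on clean runs at or below one per
batch.

## Off-line QC and statistics

`measure_printlets()` thresholds the batch photograph (Otsu by
default), labels connected components, and reports per unit the
equivalent-circle diameter `2√(A/π)` (robust to edge notches; a
max-radius alternative is a flag), circularity `4πA/P²` with the
perimeter from the traced contour polygon, dimensional accuracy
`100·(1 − |d − d₀|/d₀)`, and an edge-defect flag at circularity
< 0.85. Note the accuracy definition is this package's own (the field
uses the word loosely), and rasterized circularity can slightly exceed
1.

`compare_instruments()` (per-parameter OLS + Pearson r with its t-test
p) and `speed_effect_tests()` (one-way ANOVA, Tukey HSD at family level
0.05, and Wilks/Pillai/Roy via `stats::manova`) are thin, tested fronts
over base R. With a single response the multivariate statistics are
computed from the ANOVA sums of squares directly (`Wilks =
SSW/(SSB+SSW)`), which the tests verify against the identity. The
bundled reference tables (`reference_data()`) carry the published
characterization values for four hydrochlorothiazide formulations; the
raw replicate data behind them are not available, so published
multivariate p-values are not recomputable and the machinery is
validated on synthetic data only.

The weight generator credits each unit the deposited volume of its
toolpath times the paste density, times a small speed-linked
over-extrusion (+1 % per doubling-equivalent of the reference speed),
emulating the observed slight weight increase at higher speeds; the
weighing/process noise default is 5 mg.

## What the synthetic data does not show

The generator emulates trace shape, speed and temperature labelling,
fault signatures, batch geometry and weight/diameter dispersion. It
does **not** model: thermal dependence of rheology (temperature is a
label; callers supply different fluids per temperature), acceleration
kinematics, slip or plug flow in the nozzle, paste ageing within a
batch, or the large post-yield pressure rise of strongly
consistency-dominated pastes (see above). Passing tests therefore
validate the *analytics* — segmentation, integration, detection,
regression — under realistic but idealized signals, not the hardware
physics of any particular instrument.

## Problem sizes used by the test suite

The suite runs the full 70-unit batch once for directionality checks,
twenty 70-unit fault-injection runs plus twenty clean runs for the
detector's sensitivity/specificity property, and sixty
compression-cycle simulations (20 seeds × 3 speeds) for parameter
recovery — about one minute end to end. Characterization traces sample
at 5 Hz, batch traces and timelines at 2 Hz; both are package defaults
chosen to resolve every feature the analytics read (the fastest
transient, the compliance relaxation, is ≈1.3 s).
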