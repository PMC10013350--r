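---
title: "Models and methods behind woundfield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind woundfield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundfield)
```

`woundfield` implements the computational stack of a bioelectronic
microfluidic scratch-wound assay: electric-field and joule-heating models of
the microchannel network that carries the cells, charge budgeting for the
pseudocapacitive electrodes, colorimetric pH readout from an indicator
coating, and quantitative analysis of the time-lapse imaging (closure
curves, kymographs, track directedness). A seeded synthetic-data generator
provides ground-truthed stand-ins for the microscope data, so every analysis
stage can be validated end-to-end without raw experimental images.

This vignette records the models, the defaults and the design choices that
were genuinely open, in enough detail that a maintainer can judge what the
package does and does not claim.

## Chip geometry

Three parametric layouts are provided: a straight channel, a t-junction, and
a four-branch "peace sign" in which two anode-containing branches meet the
cathode branch at ±45°, plus a 0.9 mm "scratch runway" branch sized for a
p10 pipette wounding tool. Coordinates are millimetres, origin at the
junction, x right and y up. The published device reports only the runway
width (0.9 mm) numerically; the remaining cross-sections are figure-only,
so the package adopts canonical defaults — 0.9 mm width for all branches,
0.08 mm channel height, 5 mm branch length, 2 mm reservoir radius — all
overridable. With ±45° anode branches and 2 mm reservoirs, 5 mm anode
branches would make the anode-end reservoirs overlap the runway reservoir,
so the anode branch default is 7 mm; `chip_layout()` validates reservoir
clearance and rejects non-positive dimensions. Because the cross-section is
assumed rather than measured, absolute network resistances are validated
against closed forms, not against the published 3-D finite-element values
(101.6 and 108.3 kΩ, which include reservoir and electrode geometry that is
not printed); at the defaults the model gives ≈ 86 kΩ for the
uni-directional path, the right order but not a reproduction.

`rasterize_layout()` discretises the network onto square cells. Channel
segments are filled as rectangles (plus a junction disc where branches
meet), reservoirs as discs, and each conducting cell carries the sheet
conductance σ·h — the thin-film (2.5-D) approximation, justified because
the channel height (0.08 mm) is tiny against the lateral extent (millimetres).
The grid must resolve the narrowest channel with at least six cells
(`spacing ≤ width/6`); the rasterised conducting area converges to the
polygon area at first order in the spacing, which the tests check on an
angled branch.

## Electric-field solver

`solve_field()` solves steady current conservation ∇·(σh∇V) = 0 with a
five-point stencil, harmonic-mean interface conductances, insulating walls,
uniform current injection over the active anode footprint (a 1 mm disc in
the reservoir) and withdrawal at the cathode, with the gauge fixed by
pinning one cathode cell. The sparse symmetric system is solved directly
(Cholesky), so results are deterministic and the residual is at
floating-point level. E = −∇V is reported in mV mm⁻¹ (numerically equal to
V m⁻¹), J = σE, and the per-cell areal dissipation is accumulated from edge
currents so that its total equals I²R *exactly* in the discrete system —
this is what couples the thermal solve consistently.

The electrolyte default is 1× phosphate-buffered saline, σ = 1.54 S m⁻¹.
A straight 0.9 × 0.08 mm channel at 25 µA has the closed-form mid-channel
field E = I/(σwh) = 225.5 mV mm⁻¹, which the solver reproduces to
numerical precision; `calibrate_current()` exploits linearity (one probe
solve, one confirming solve) and returns σ·E·A for the uniform channel.
On the peace-sign chip at the defaults, 25 µA gives ≈ 196 mV mm⁻¹ at the
wound centre — consistent with the design target of roughly 200 mV mm⁻¹
at the published protocol current.

The `dead_zone_ratio()` metric (wound-centre |E| over the mean |E| in a
reference branch, reservoir-covered cells excluded) quantifies why the
layout matters: with both anodes driven simultaneously, the t-junction
short-cuts the bend and leaves the junction wound at a ratio of ≈ 0.3,
while the angled peace-sign branches keep it at ≈ 0.8, and a straight
channel sits at 1 by construction. The pseudo-converging protocol itself
activates exactly one anode at a time (`relay_sequence()`, 30 min default
period); the x-component of the wound-centre field flips sign between
consecutive intervals, which is the property the relay exists to produce.
The simultaneous multi-anode drive is retained as an explicit `state =
"all"` option because the dead-zone comparison needs it.

## Joule heating and dosimetry

`joule_energy()` is the protocol energy I²Rt: 25 µA across 101.6 kΩ for
12 h gives 2.74 J, and 20 µA across 108.3 kΩ gives 1.87 J.
`disc_current_density()` reports mA cm⁻² for disc electrodes (0.40 mA on a
3 mm disc is 5.7 mA cm⁻², about 250× the 25 µA/12 mm chip value), and
`capacitive_duration()` is the t = q/i capacitive budget, with q = CSC·area
(a 12 mm disc at 40 mC cm⁻² stores 45.2 mC, so 25 µA can be delivered
capacitively for ≈ 1810 s). `relay_charge_budget()` tracks each anode's
state of charge through the relay protocol, with a configurable
`recharge_fraction` (default 0.9; no published value exists) for the
passive ionic recharge of the idle anode, and flags the phase at which
cumulative net discharge would exceed the stored charge.

`transient_heat()` bounds the wound-zone temperature rise with a 2.5-D
transient solve on the chip grid. Every cell carries lumped acrylic
substrate and lid layers (defaults 1 and 8.5 mm); conducting cells
additionally carry the electrolyte film and the areal joule source from the
field solution. Heat spreads laterally through electrolyte and acrylic and
leaves vertically through lid and substrate in series with surface
convection (h = 5 W m⁻² K⁻¹ into a 310.15 K environment; an optional
linearised radiative term with emissivity 0.95 is off by default, being
negligible for sub-kelvin rises). Time stepping is backward Euler with the
constant system factorised once; the tests pin the solver against the exact
uniform-source steady state p/U and the fin-equation profile of a
half-heated strip.

Material properties follow the published finite-element model: PBS
k = 2 W m⁻¹ K⁻¹ and ρ = 1000 kg m⁻³, acrylic k = 0.19 W m⁻¹ K⁻¹,
ρ = 1190 kg m⁻³, Cp = 1420 J kg⁻¹ K⁻¹. Two deliberate deviations: the
printed electrolyte heat capacity of 4 J kg⁻¹ K⁻¹ is treated as a unit
anomaly and the default is water's 4184 J kg⁻¹ K⁻¹ (any value can be
configured; the steady-state rise is Cp-independent, which the tests
verify, so the bound is unaffected), and the printed k = 2 W m⁻¹ K⁻¹ is
kept although bulk water is nearer 0.6 — using the larger printed value
only speeds lateral spreading. At 25 µA for 12 h on the peace-sign chip the
maximum wound-zone rise is ≈ 0.02 °C, comfortably below the 0.1 °C bound
the thermal analysis exists to establish. The published per-case maxima
(0.03/0.11 °C) depend on the unprinted 3-D geometry and are not
reproduced. One published comparison — higher dissipation density in the
pseudo-converging case due to its narrower branch — has no analogue here
because all default branches share one width, so it is not tested.

## pH colorimetry

The indicator coating (polyaniline) maps pH to hue, green in acid to purple
in base. `mean_hue()` averages R, G, B over the region first and converts
the mean colour to hue (the alternative, averaging per-pixel hues, differs
and is not used); hue is invariant to uniform brightness scaling, and an
achromatic mean returns 0° with a flag. Hues here span roughly 60–300°, so
no circular statistics are needed; values near the 0°/360° wrap would be
flagged by the calibration domain instead.

The calibration model is the bi-dose-response curve — two logistic
transitions sharing asymptotes:

hue(pH) = A1 + (A2 − A1)·[ p/(1+10^{h1(logx01−pH)}) + (1−p)/(1+10^{h2(logx02−pH)}) ].

The published work names this fit but not its parameter values, so the
package both fits it (`fit_calibration()`, Levenberg–Marquardt with
heuristic initialisation from the extreme hues and the 25%/75% crossings;
deterministic; at least 8 distinct pH points required, the published
calibration used 15) and forward-simulates it (`ph_curve()` with defaults
A1 = 80°, A2 = 280°, centres at pH 6 and 9.5, unit slopes, p = 0.5).
Synthetic-recovery tests at 2° hue noise over 20 seeds recover the
asymptotes and centres within 10%. `hue_to_ph()` inverts by root finding on
the calibration domain (tolerance 10⁻⁴ pH) after a numeric monotonicity
check; out-of-range hues are clamped to the domain edge, returned with a
warning and an `extrapolated` flag. `roi_ph_traces()` applies this
per frame and per region, and reports the wound-zone trace as the mean of
the in-channel regions, mirroring how the assay is read out.

## Wound-closure analysis

`segment_wound()` replaces the interactive ImageJ-plugin step of the
original workflow with a deterministic, parameterised operator: a
sliding-window standard deviation (21 px window, via integral images) maps
local texture; Otsu's threshold splits smooth from textured; a morphological
closing (5 px disc) and a largest-component rule keep the low-texture region
that straddles the declared wound axis. Because the window elevates texture
within its half-support of any cell and the Otsu split lands partway up that
ramp, the selected region is eroded by roughly half the window radius; the
operator dilates that amount (window/4) back. Two guards make degenerate
inputs explicit rather than silent: a frame whose texture distribution is
unimodal (low/high class-mean ratio above 0.5) contains no wound boundary
and is reported as whole-frame wound ("degenerate") if its texture level is
at the bare-substrate floor, or as no wound ("empty") otherwise. Only that
tie-break uses an absolute texture level (0.02 intensity units); frames that
contain a wound are segmented scale-invariantly, so closure percent is
unchanged by affine intensity rescaling.

`closure_curve()` normalises each frame's wound area to the first frame and
reports closure percent; negative closure is flagged as wound expansion,
and a zero first-frame area is an error rather than a silent NaN.
`closure_rate()` is the least-squares slope of closure percent against
time, fitted from the start until the wound first reaches 95% closed (so a
closed, flat tail does not dilute the estimate), or over all frames
otherwise. `kymograph()` averages 7 evenly spaced horizontal lines in the
wound ROI per frame (half-spacing margins at the ROI edges) and stacks one
row per frame — a 12 h stack imaged every 10 min has 72 frames at t = 0,
10, …, 710 min and therefore yields exactly 72 rows. `directedness()`
computes, per frame-to-frame step, the cosine of the displacement angle to
the +x field axis (+1 rightward/cathodal, −1 leftward, 0 undirected),
skipping zero-displacement steps; the per-cell mean step cosine is the
headline statistic and the net-displacement cosine is reported alongside,
since either reading of "displacement angle" is defensible. Cells that
never move are flagged and excluded from cohort means.

## Synthetic data: what it does and does not show

`simulate_collective()` is a persistent random walk with drift, chosen as
the simplest generator that exhibits the observables the analysis measures
— directedness, closure, relay-driven direction reversal — while making no
mechanistic claim about electrotaxis. Two confluent sheets flank a central
gap; each cell's heading mixes persistence (0.6), a random unit turn and a
bias term β toward +x (sign schedulable per step for relay scenarios);
sheet fronts advance at the speed implied by a prescribed true closure rate
(the quantity under test), cells are carried with their front, free-edge
cells receive a small gap-ward protrusion (the stand-in for free-edge
motility, so unstimulated controls also close), and pairwise exclusion
resolves overlaps. Scenario defaults follow the published study design:
12 h at 10 min intervals, closure rates of 1.0, 2.8 and 3.5 % h⁻¹ as the
inhibited/stimulated/healthy scenario values, and a motility factor < 1 for
inhibited cultures. Defaults are 512×512 px with 8 px cell radius; the test
suite and acceptance script run 256×256 px with 6 px cells — stated here as
the package's chosen validation scale — and the recovery tolerances hold at
both.

`render_stack()` draws cells as bright-rimmed, speckled discs on a smooth,
slightly shaded background with mild Gaussian noise, so the cell-free gap
is the only low-texture region — by construction the feature
`segment_wound()` detects. Ground truth is exact: the true wound band
follows the prescribed fronts, the true rate is the prescribed slope, and
the generator is bit-deterministic given its seed. End-to-end, the pipeline
recovers ground-truth closure rates within ±0.5 % h⁻¹ and segmentations
overlap the true band with IoU ≥ 0.9.

The directedness response to β saturates (beyond β ≈ 0.3 nearly every step
points gap- or field-ward, and front clamping truncates further gains), so
monotonicity is asserted across bias levels in the responsive range
(0–0.4); unbiased cohorts of ≈ 240 cells stay within ±0.05 of zero.

What passing these tests shows is that the *analysis* is correct and
well-calibrated on data whose truth is known. It does not show that the
generator reproduces real phase-contrast statistics (halo artefacts,
uneven illumination, cell divisions, track errors), and the published
experimental closure percentages depend on the raw microscope data, which
no generator can stand in for; they are used only as scenario parameters.

`synthetic_ph_stack()` forward-models the indicator readout: per-pixel hue
from the bi-dose-response curve at the local pH plus Gaussian hue noise at
fixed saturation/value, in full floating-point colour so that the noiseless
round trip is exact to the inversion tolerance; with 2° hue noise the
recovered pH is within 0.05 units.

## Numerical choices and limitations

* All randomness flows through explicit seeds; generators save and restore
  the global RNG state.
* The field and heat systems are solved directly (sparse Cholesky); there
  is no iteration to tune and no tolerance to miss. Current conservation
  through any anode/cathode cut holds to ~10⁻¹² relative; the tests demand
  10⁻⁶.
* The wound "centre" is the centroid cell of the wound-zone mask, snapped
  to the nearest conducting cell; profiles are nearest-cell lines, not
  interpolated.
* Grid defaults: 0.05 mm spacing for field work (the wound-centre field
  moves < 1% under halving), 0.15 mm for the coupled thermal solve with a
  2 mm bare-plastic margin; 120 s backward-Euler steps (the thermal time
  constant is ≈ 30 min, and steady state is Cp-independent).
* The 2.5-D approximations (sheet conductance, lumped acrylic layers)
  reproduce closed forms and bounds, not the published 3-D absolute values;
  that distinction is kept explicit throughout.
* Tracks are inputs (or simulator outputs); the package does not do cell
  tracking or single-cell segmentation, and no illumination correction
  beyond the mean-RGB hue readout is attempted.
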