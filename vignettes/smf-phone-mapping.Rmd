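---
title: "Methods: SMF mapping, source modelling and head dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SMF mapping, source modelling and head dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfmap)
```

## The measurement and its processing

A phone lies below a mapping plane; a tri-axial magnetometer samples the
field on a 120 × 200 mm grid at 10 mm pitch (13 × 21 nodes), in triplicate,
at heights z = 15, 20, 25, 30 and 55 mm above the screen, plus triplicate
background-only maps. The coordinate frame has its origin at the screen
centre, x across the width, y along the length (positive toward the
speaker), z along the outward screen normal.

The processing order is fixed and deliberate: **average replicates
component-wise → subtract the averaged background vector-wise → take the
magnitude**. Magnitudes do not commute with either step: |a − b| ≠ |a| − |b|
and the mean of magnitudes is not the magnitude of the mean, so the pipeline
keeps vectors as long as possible and the test suite asserts the
counter-examples. The repeatability SD, by contrast, is computed on the
replicate *magnitudes*, because it feeds an uncertainty on |B|, which is the
reported quantity.

Hot spots are 8-neighbourhood local maxima of the background-free magnitude
map exceeding the map median by a prominence margin (default three times the
median per-node SD), at most one each in the upper (y > 0) and lower
(y < 0) half of the screen. The hot-spot node found on the lowest map is
held fixed across heights when the decay curve is assembled.

## Uncertainty budget

Four components are combined in quadrature at every (hot spot, height):

| component | meaning | default |
|---|---|---|
| `sd` | replicate repeatability of \|B\| | measured |
| `u_zero` | sensor zeroing error | 2 µT |
| `u_cal` | calibration error × reading | 0.5 % |
| `u_grad` | \|dB/dz\| × z-position uncertainty | slope × 1.6 mm |

The z-position uncertainty is 1.5–1.7 mm; the package uses the midpoint
1.6 mm. The slope entering `u_grad` comes from finite differences of the
*measured* curve (one-sided at the ends, central inside), so the error bar
assumes no source model. Near the screen `u_grad` dominates; at 55 mm, where
the field is ~10–40 µT, the 2 µT zeroing floor becomes the leading term.

## Decay models and fitting

All three families are fit by least squares on the original µT scale —
no transformation, no weighting by default (a 1/Uc² weighting option
exists). R² is always reported unweighted on the original scale. Rationale:
near-screen points then dominate the fit, which is where the extrapolation
target `B@0` lives, and the reference R² values this package is tested
against are near 1 on that scale.

The SLC fit minimizes over (r, I) with `mu_r` held at 5000: the core
permeability multiplies the current everywhere, so (mu_r, I) is a ridge and
only the product is identified; fits at `mu_r = 1` recover exactly 5000× the
current (asserted in the tests). Optimization uses bounded
Levenberg–Marquardt (minpack.lm) from r₀ = 8 mm and the current that passes
the model through the first curve point, with bounds r ∈ [1, 30] mm,
I ∈ [0.05, 200] mA (scaled for other `mu_r`) and up to five restarts that
perturb r₀ by fixed factors (±25 %, ±50 %) — deterministic, so identical
inputs give identical fits. Constant curves (SStot = 0) are rejected rather
than fit.

The threshold distance solves |dB/dz| = 0.02 mT/mm by bracketed root
finding on [0, 200] mm to 10⁻³ mm. The gradient magnitude is strictly
decreasing there for every bundled parameter set (checked numerically), so
the root is unique; a gradient already below threshold at the screen returns
0 with a flag.

## The 3D field engine

Off-axis fields come from the Biot–Savart line integral over the circular
loop, evaluated by the midpoint rule with `n_segments` elements (default
360). For a smooth periodic integrand this quadrature converges extremely
fast, and on the axis it is exact by symmetry, so the closed form above is
reproduced to near machine precision; the documented guarantees (0.1 % at
360 segments, 10⁻⁵ at 3600) are loose upper bounds. The `mu_r` multiplier
is applied as a uniform scalar prefactor to the free-space field — the same
idealization the closed form makes, not a magnetostatic boundary-value
solution for a real core; absolute fields inherit that idealization, while
ratios and positions (dynamic range, cancellation loci) are insensitive
to it.

The head fixture is an icosphere (20·4ᵏ faces, default k = 3) scaled to an
ellipsoid; it is watertight with outward analytic normals. The calling pose
places the screen plane parallel to the head's tangent plane at the
maximum-x "ear" vertex, shifted along that plane so the **upper hot spot
(the speaker) sits opposite the ear** — with the screen centre at the ear
the speaker would hover ~70 mm above it, where the head has curved away and
the near-field mT exposure would be lost. The 5 mm standoff stands for ear
anatomy the ellipsoid lacks.

The hypomagnetic-zone search scans the requested box at 2 mm, refines the
few lowest well-separated candidates by coordinate descent with step
halving to 0.01 mm, and keeps points with |B_total| < 1 µT. With a
background antiparallel to a loop axis and a magnitude between the on-axis
field at the box boundaries, the on-axis cancellation point is always found
(property-tested against inverting the closed form).

## The synthetic generator

`simulate_study()` emulates the protocol's error structure, not just its
geometry:

- **per-reading sensor noise**, Gaussian, 0.1 µT RMS per axis (the ambient
  AC noise figure; the sensor's intrinsic floor is not separately known);
- **per-session systematics**: one zero-offset draw per axis (uniform in
  ±2 µT) and one calibration scale draw (uniform in ±0.5 %), shared by all
  maps of a session — zeroing is a bias, not white noise, and because the
  background maps share it, vector background subtraction removes it, which
  is exactly why it must still be carried in the uncertainty budget;
- **per-map z jitter**, sd 0.3 mm, perturbing the *true* evaluation height
  while the recorded nominal height stays clean — this is the physical
  origin of the `u_grad` term. The value is the repositioning repeatability
  one expects of a machined spacer stack; the larger 1.5–1.7 mm figure is
  the *systematic* bound on the absolute z position and enters the budget
  (`delta_z`), not the per-map scatter. Screen extrapolation is quite
  sensitive to this choice: per-map white jitter at the full 1.6 mm scale
  would make `B@0` recovery scatter several-fold.

Seeds derive deterministically per map from the dataset seed; identical
inputs give bit-identical datasets. What the generator does **not**
emulate: sensor quantization, temperature drift, lateral (x, y) placement
error of the hand-positioned sensor — the last is probably the main reason
real replicate SDs near a steep hot spot are far larger than 0.1 µT. Passing
the recovery tests therefore shows the pipeline is unbiased under the
modelled error structure, not that real-world uncertainties are this small.

A forward-model subtlety the tests document: with both of a phone's magnets
in the truth, the decay curve over one hot spot contains the other loop's
partially cancelling far field (about −9 % of the signal at z = 55 mm for
the reference model 1). A single-source fit then carries a few percent of
cross-talk bias in `B@0`. The exact round-trip identity (recovery to 10⁻⁴)
therefore holds per source — asserted on single-loop truths — while the
two-loop pipeline is asserted to land within the cross-talk envelope (~6 %).

## Reporting conventions and configuration

Files and interfaces use µT, mm, mA; SI is internal only. `B@0` is reported
in mT, power-law `a` in µT, exponential `a` in mT. Comparisons against the
bundled reference tables are made at their printed precision (the printed
parameters are themselves rounded; e.g. reference `(r, I, T)` reproduce a
printed screen field of 6.60 mT as 6.605). Configuration is a single
plain-text YAML document (`write_study_config()` / `read_study_config()`);
YAML was chosen as the environment's available key-value format. All
constants (mu_r, threshold, budget terms, skull depth 4 mm) live in the
config, never in stage logic.

## Problem sizes

The test suite exercises the protocol-sized grid (13 × 21, five heights,
triplicates) throughout; the Monte-Carlo recovery check uses 50 seeded
studies; convergence of replicate scatter uses 1000 background maps on a
5 × 5 grid; head maps use the k = 3 icosphere (642 vertices). These sizes
were chosen so each property is measured well inside its tolerance while the
whole suite stays quick to run.

## Known limitations

- One source per hot spot; no joint multi-loop fit that would remove the
  cross-talk bias.
- The permeability prefactor idealization above; fitted currents are
  effective parameters of that idealization, not physical coil currents.
- The ellipsoid head is a geometric stand-in: fine for dynamic-range and
  cancellation topology statements, not for anatomical dose at a tissue.
- The decay curve is on-axis by construction; off-axis decay is only used
  through the 3D engine, never fit.
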