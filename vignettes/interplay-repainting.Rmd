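---
title: "Simulating the interplay effect and selecting volumetric repaintings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the interplay effect and selecting volumetric repaintings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repaintr)
```

`repaintr` simulates the interplay between pencil-beam-scanning (PBS)
proton delivery and breathing motion for lung-like targets, and selects
the number of alternating-order volumetric repaintings needed for an
acceptable plan. This vignette is the package's account of the model:
what is simulated, which parameters matter, where the design was
genuinely open, and what the simulation can and cannot say about real
patients.

## The delivery and motion model

A plan is a set of beams, each an ordered list of energy layers
(distal to proximal, strictly descending energy) holding weighted spots
at the isocenter plane. Delivery is serial: a spot dwells
`mu × 4 ms/MU`, the beam moves to the next spot at 250 cm/s (beam off),
and every energy change costs 1.0 s. These four machine constants —
scanning speed, dwell time per MU, a 0.015 MU minimum spot weight, and
the layer switching time — define the entire time structure
(`machine_model()`). A fast-switching beamline is assumed in both the
"down" and "up" directions; an asymmetric pair of switching times can
be configured, but the default uses the single common value.

Breathing is a ten-phase cycle of period 4.0 s (a typical adult
free-breathing value; configurable) with equal phase dwell. The CTV
moves rigidly; each axis follows
`(A/2)·cos(2πk/10)` over phases `k = 0…9`. The cosine is a surrogate —
clinical 4DCT reports phase bins, not waveforms — chosen because it is
the standard phase-binning idealization: phase 0 and phase 5 are the
motion extremes, the mean over phases is zero, and the per-axis range
equals the configured peak-to-peak amplitude exactly. Equal dwell time
per phase is likewise an idealization of amplitude-binned data.

The phase active at any instant is
`(starting_phase + floor(t / (period/10))) mod 10`. Because delivery can
begin at any point of the cycle, the evaluation enumerates all ten
starting phases; each is one scenario. Each sub-spot is looked up at its
temporal midpoint and not split across phase boundaries: spot durations
are a few milliseconds against a 0.4 s phase dwell, so the approximation
error is negligible. Every field's clock restarts at the scenario's
starting phase (inter-field dead time is machine- and workflow-specific
and deliberately not modelled).

## The synthetic 4D phantom

`generate_phantom()` voxelizes an ellipsoidal CTV on a regular grid
(default 3 mm, mirroring a typical dose-grid resolution) inside a
homogeneous lung-like slab (relative density 0.26) behind a
water-equivalent entry depth (default 50 mm). The voxelization keeps
exactly `round(V/h³)` centers innermost in the ellipsoidal norm, so the
generated volume matches the request to within one voxel volume for any
shape. Optional seeded Gaussian jitter of the voxel centers (sub-voxel,
e.g. 0.5 mm) emulates contouring and voxelization variability between
otherwise identical cases; all other geometry is deterministic.

The defaults describe the envelope of typical PBS lung cases: CTV
volumes of tens of cc (valid range tested up to ~180 cc), 3D motion
magnitudes of roughly 4–13 mm, with a hard refusal above 15 mm (bigger
motion calls for different mitigation strategies) that can be overridden
with a warning.

What the phantom does *not* emulate: tissue deformation (motion is a
rigid translation, which makes dose accumulation by voxel tracking
exact and needs no deformable registration), CT image content or HU
calibration, heterogeneity beyond the two-density geometry, and
irregular breathing (period drift, baseline shift). Passing tests
therefore demonstrate the mechanics of interplay and its mitigation,
not patient-specific dosimetry.

## Dose engine

The engine is an analytic pencil-beam kernel evaluated only at the CTV
voxel centers (every evaluation metric is a CTV metric):

* **Range–energy**: Bragg-Kleeman `R = αE^p` with `α = 0.0022 cm/MeV^p`,
  `p = 1.77` (standard water values; 100 MeV → 7.6 cm, 226.5 MeV →
  32 cm, deeper than any phantom used).
* **Depth dose**: an entrance plateau (30% of peak) rising as a
  Gaussian into the peak (exactly 1 at `z = R`) with a Gaussian distal
  falloff (σ = 2.2 mm); dose is below 2% of peak beyond 3σ. The
  80%–80% peak width of this curve (≈3.3 mm) doubles as the energy-layer
  spacing, mimicking the automatic TPS rule that derives layer spacing
  from the Bragg-peak width.
* **Lateral**: a normalized 2D Gaussian with
  `σ² = σ_air² + (0.5 mm/cm × depth)²` — a 3 mm in-air sigma growing
  with water-equivalent depth.
* **WEPL**: closed-form line–ellipsoid intersection — entry depth, lung
  path at 0.26, tumor chord at 1.0 — re-evaluated per breathing phase.
  Because voxels and the density ellipsoid move together, transverse
  motion changes only the lateral coordinates and along-beam motion
  shifts WEPL by the lung-density-weighted displacement; both are
  covered by unit tests.

The kernel scale (5000 cGy·mm²/MU) puts per-fraction spot weights
around 0.1–0.3 MU — the clinically typical range — which matters
because the minimum-MU rule determines how finely spots can be
repainted. There is no Monte Carlo transport, nuclear halo, or range
shifter; Monte Carlo statistical settings (ions per spot, statistical
uncertainty) have no analytic analogue here. All evaluation metrics are
relative or DVH-shape quantities, which is why a smooth analytic kernel
is an adequate desk-scale stand-in.

## Planning

`generate_sfud_plan()` builds 2–3 coplanar fields (default gantry 0°
and 90°). Per beam: energy layers span the CTV's WEPL extent plus a
0.6-width margin; each layer's spots sit on a lateral grid of one
in-air sigma (3 mm), kept within 4 mm of any CTV voxel whose WEPL lies
within 0.75 widths of the layer range; within a layer the scan order is
serpentine. Spot weights are solved per beam by nonnegative least
squares against a uniform target of `fraction dose / n_beams` on the
reference-phase CTV voxels, using multiplicative (ISRA) updates —
monotone in the objective, nonnegativity-preserving, and exact in one
step for decoupled systems. Spots that optimize below 0.015 MU are
removed and the remainder re-solved once (one-pass policy), then any
stragglers are clipped up to the minimum.

The plan is then normalized by a single scalar so the nominal static
D99% equals 6930 cGy(RBE) — 99% of the 7000 cGy(RBE) prescription.
Dose is linear in MU, so the scaling is exact and idempotent, and
every "nominal" term of the metrics refers to this distribution.

Each field alone delivers a near-uniform CTV dose (coefficient of
variation below 5% on the reference phase) — the SFUD property, checked
by `plan_uniformity()`. Gantry angles, spacing rules and margins are
surrogates for proprietary TPS machinery and are all configurable in
`planning_config()`.

## Repainting and its constraints

`build_vrx_plan()` divides each spot across paintings with
`split_spot_mu()`: a spot of weight `w` appears in
`k = max(1, min(X, floor(w/0.015)))` paintings at `w/k` each, so every
emitted sub-spot remains deliverable. When `k < X` the spot's paintings
are spread evenly over `1..X` (indices `round(jX/k)`) rather than
bunched at the start, preserving temporal averaging — the motivation for
repainting in the first place. The last sub-spot absorbs the floating
point remainder so each spot's MU is conserved to one ulp.

Painting 1 traverses layers down, painting 2 up, and so on; at each
junction the boundary energy is delivered twice in a row and no switch
time is charged. Layers with no surviving spots in a painting are
skipped. The spot order within a layer is identical in every painting —
the machine's behaviour between paintings is not standardized, and
identical order is the conservative choice (no extra averaging is
credited to order shuffling).

## Metrics and the verdict

`dose_at_volume()` defines D_X% as the dose received by at least X% of
the equal-volume voxels — the `ceil(Xn/100)`-th largest dose. This
inverse-cumulative step convention was chosen over interpolation
between order statistics because it agrees with a brute-force
cumulative histogram at arbitrarily fine binning, which the test suite
enforces to 0.02 cGy against a 0.01-cGy-bin oracle.

The seven metrics and their conventions:

* WCS selection: minimum over the ten scenarios for coverage and HI,
  maximum for the hot-spot D1%.
* ΔD1% is normalized by the *nominal D1%*; the coverage changes ΔDX%
  by the *prescription*. The two denominators are deliberately
  different and pinned by unit tests.
* DVH bandwidth at DX% is the max−min across the ten scenarios — the
  natural width of the scenario band. (A percentile spread would be an
  alternative reading of "width"; max−min is used throughout.)
* Bandwidth averages run over X = 95…99 (coverage) and X = 1…5
  (high dose).

Classification: coverage bounds are inclusive at CR1 (D95% exactly 98%
passes CR1); change/bandwidth bounds are strict at CR1 (ΔD1% exactly
1.5% falls to CR2). The boundary ΔHI = 0.030 is assigned to CR2 — the
printed interval is open there, but a total classification requires a
closed lower bound, and CR1's strict `< 0.030` forces the value into
CR2. A plan is acceptable when all seven metrics meet CR1, acceptable
with a minor deviation when at least five meet CR1 and every metric
meets at least CR2 (CR1 membership counts as meeting CR2 — otherwise
the rule would be unsatisfiable), and unacceptable otherwise; this
includes the edge case of a plan at the painting limit with fewer than
five CR1 metrics, which has no dedicated label and is reported
unacceptable. `find_optimal_repaintings()` escalates X = 1, 2, … and
never skips an X, so the reported X* is minimal by construction.

Scenario doses are single-fraction interplay patterns scaled by the 35
fractions: DVHs and thresholds all live on the course-dose scale, and
no inter-fraction averaging is credited — each scenario is a worst-case
realization in which every fraction starts in the same phase.

## Numerical choices and degenerate inputs

* Normalization is exact (one scalar; D99 reproduced to better than
  1e-9 cGy) and refuses all-zero dose.
* `split_spot_mu()` refuses weights below the machine minimum — a
  nominal plan must already be deliverable; floor computations carry a
  1e-9 slack against floating point.
* Empty beams are an error in `plan_statistics()`, not a zero row.
* Single-spot layers at painting junctions produce a zero travel gap;
  timestamps still increase strictly because dwell times are positive.
* The motion-free limit is exact to machine precision: with zero
  motion every scenario equals the static dose, all deltas and
  bandwidths vanish, and X* = 1.
* MU bookkeeping per scenario (MU scored while each phase was active)
  reproduces the plan MU to 1e-12 relative.

## Problem sizes

The test suite and examples run CTVs of ~22–30 cc at 3–4 mm voxel
spacing (≈350–1100 voxels, 11–17 layers and ~600–1700 spots per beam),
two fields, and full ten-scenario sweeps; the statistical
mitigation check uses five jittered phantom realizations at 10 mm SI
motion, comparing X = 1 against X = 8 by median bandwidth and WCS
D95%. These sizes were chosen so the whole evaluation of one plan takes
seconds while keeping layer/spot counts and delivery times (roughly
1–4 min per beam for repainted plans) in the clinically reported range.

## Known limitations

* **No 4D-robust planning.** Weights are optimized on the reference
  phase only. A clinical 4D-robustly optimized plan guarantees target
  coverage in every phase if delivery were instantaneous, so its
  residual degradation is purely interplay; here, part of the coverage
  loss under large motion is systematic blur that no number of
  repaintings can recover. Consequently, for larger motions the
  coverage WCS can saturate below CR1 at the painting limit and the
  honest verdict is "unacceptable" — the escalation bookkeeping, not a
  defect. Hot-spot, homogeneity and bandwidth metrics still converge
  with increasing X.
* Rigid motion only; no deformation, no baseline drift, no irregular
  breathing.
* The analytic kernel has no nuclear halo or heterogeneity scatter;
  absolute doses are only meaningful through the normalization anchor.
* Layered (iso-energy) repainting and breath-sampled repainting are
  out of scope; only volumetric repainting with an alternating order is
  sequenced.
* OAR metrics and biological indices are not computed; every metric is
  a CTV DVH quantity.
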