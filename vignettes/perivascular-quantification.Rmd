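---
title: "Quantifying perivascular oligodendrocyte-vessel association in 3D volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying perivascular oligodendrocyte-vessel association in 3D volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perivasc)
```

## The measurement problem

A sizeable minority of mature oligodendrocytes in the adult brain sit with
their cell body directly against the vasculature, mostly on capillaries,
in contact with the vascular basement membrane. Establishing that claim
quantitatively requires a chain of measurements on multi-channel confocal
stacks: how far is each cell body from the vessel wall, what fraction of
cells falls below an association threshold, does that fraction exceed
chance, on which vessel calibers do the cells sit, how does the population
distribute with cortical depth, and do vessel-associated cells differ
electrophysiologically from other oligodendrocytes.

`perivasc` implements this measurement chain as a tested pipeline and — since
the original tissue stacks are not available — ships a synthetic-volume
generator with analytic ground truth, so every stage can be validated
against known answers. The synthetic scenes are first-class citizens: the
acceptance checks run the full pipeline on them and compare the recovered
quantities with the generating truth.

## Distance semantics: peak-to-peak, not surface-to-surface

The association measurement mirrors the line-tool convention used on real
images: a line is cast from the cell-body centroid through the nearest
centerline point of the vessel network and past the far wall; every channel
is sampled along it by trilinear interpolation (spacing one quarter of the
smallest voxel). The distance between a cell and a wall marker is the
distance between the *fluorescence intensity peaks* of the two channels
along this line. A cell is vasculature-associated (a "vOL") when its
minimum marker peak distance is at most 1 µm, boundary inclusive.

Peaks are refined to sub-sample precision with a three-point parabolic fit
(switchable via `refine_peaks`, to mimic pixel-resolution maxima). Two
search windows stabilize the peak choice: the wall-marker peak must lie
within a window (default ±3 µm) of the expected wall crossing, and the cell
peak is sought anywhere between the centroid and just past the wall — a
detached soma legitimately peaks far before the wall, and that distance *is*
the measurement. Exact ties between equidistant vessels resolve to the
lowest edge id.

## The phantom: what it emulates and what it does not

`phantom_params()` + `simulate_phantom()` build a multi-channel volume:

* **Vessel network** — random-walk centerline polylines with a per-length
  branching probability, calibers drawn from a three-class mixture
  (capillary < 8 µm, intermediate 8–15 µm, large > 15 µm; capillaries
  dominate by default, as in cortex where most vessels are micro-vessels).
  No published network statistics beyond the caliber classes were
  available, so branch density and tortuosity are conventional choices
  (`branch_prob`, `bend_sd`), not fitted values.
* **Wall-marker shells** — Gaussian ridges at configurable offsets inward
  from the soma-facing wall: pericyte-like 0.5 µm, endothelial-like
  0.3 µm, basement-membrane-like 0.08 µm. These offsets reproduce the
  published ordering in which the basement-membrane marker is closest to
  attached somata. Shells are rendered on the *minimum-distance field* of
  the whole network; rendering them per segment would fill tube interiors
  with spurious end-cap intensity.
* **Somata** — membrane-weighted spheres (dim interior fill plus a
  Gaussian membrane ridge peaking exactly on the surface, as for a
  CNPase-like label). An attached soma is clipped where it would penetrate
  within its wall gap of the host vessel, so it wraps onto the wall over a
  spherical cap; the default cap half-angle (0.76 rad) makes the contact
  patch about 14 % of the soma surface, the scale reported for real
  somata. Attached somata sit at wall gaps ≤ 0.03 µm, detached somata at
  > 2.2 µm — a deliberate clear margin on both sides of the 1 µm
  criterion. `placement = "random"` drops the vessel-distance constraints
  entirely; that scene calibrates the chance-association null.
* **Myelin** — a depth-weighted random filament texture; soma placement
  density rises with cortical depth by the same `depth_gradient`.
* **Image formation** — Gaussian PSF blur (anisotropic, axial > lateral)
  followed by Poisson shot noise and additive Gaussian read noise.
  Ridge widths never drop below 0.8 of the in-plane voxel: features
  narrower than the sampling grid would alias and quantize peak positions.

The generator does **not** emulate: uneven illumination or depth-dependent
attenuation, marker cross-talk and bleed-through, pericyte/astrocyte cell
bodies, hemodynamics, or electron-microscopy texture. Passing tests on
phantoms therefore demonstrate that the *measurement chain* is correct and
unbiased under a realistic noise model — not that segmentation would be
robust to every artifact of real tissue imaging.

Coordinates are physical micrometres throughout; array axes are (optical z,
depth, horizontal), voxel centers at `(i - 0.5) * voxel_size`, the depth
axis is in-plane (axis 2) and the chance-association flip mirrors axis 3.

## Segmentation and vessel geometry

Masks come from an intensity threshold (Otsu on the channel histogram by
default — the source workflow set thresholds manually, which is not
reproducible — with a fixed-threshold override recorded in the config),
followed by despeckling: vessel masks drop connected components under
3 voxels, the planar myelin measure drops isolated 1×1 pixels. Both sizes
are exposed; despeckling is idempotent.

Centerlines are extracted with a TEASAR-style tracer rather than iterative
thinning: Dijkstra shortest paths whose per-length cost grows with the
depth deficit below the distance-transform ridge are traced from the
farthest unconsumed voxel back to the growing skeleton, and the tube volume
around each accepted path is consumed. Homotopic thinning variants erode
elongated tubes from their ends (we observed exactly this failure mode);
ridge-following path tracing cannot, and it yields polyline edges with
per-point radii and explicit junctions directly. Radii are read from the
local maximum of the anisotropic Euclidean distance transform around each
path point, minus a quarter-voxel discretization correction; the array
boundary counts as background so vessels cut by the stack border do not
grow medial surfaces on the cut face. Side branches shorter than 5 µm
(`prune_len`), branches that never leave their host tube, and attachments
within one local radius of an open tube end are discarded as tracing
artifacts. Very thick vessels (diameter comparable to the stack depth)
still fragment into several collinear edges; diameter readouts use local
medians and are unaffected, but branch-node counts on such vessels should
not be over-interpreted.

Somata are segmented by smoothing, thresholding and 3D connected-component
labeling; each detection carries a watertight marching-tetrahedra mesh
extracted from the smoothed intensity at the threshold level. Detections
touching the volume border are flagged and excluded from association
statistics (their geometry may be truncated), never silently dropped.
Because the membrane ridge adds intensity outside the geometric surface,
segmentation meshes are dilated by a fraction of a voxel; contact-area
validation therefore uses analytically meshed shapes, and the
`contact_distance` threshold (default 0.1 µm — below optical resolution,
above mesh jitter; the original interactive tool's threshold is not
reported) should be widened toward half a voxel when measuring on
segmented meshes.

## Vessel calibers, bifurcations, contact geometry

The diameter assigned to an associated cell is twice the median centerline
radius of the nearest edge within 20 µm of the soma centroid, classified
as capillary (< 8 µm), intermediate (8–15 µm, both bounds inclusive) or
large (> 15 µm). A soma sits "at a bifurcation" when a branch node lies
within its radius plus a 5 µm tolerance — the source analysis gives no
numeric rule, so the tolerance is an explicit, configurable convention.
Contact area is measured with the soma as the primary surface: the area of
its mesh faces within `contact_distance` of the vessel surface, which
avoids overestimation from the coarser vessel surface. Wall-marker
intensity at the contact site is compared with control sites on the same
vessel at least 10 µm away (paired design).

## Depth statistics and the chance-association null

Cell occurrences are binned at 25 µm pitch from the cortical surface;
layer statistics report densities per 10^6 µm³ of *actually sampled*
volume and per-layer vOL percentages (an empty layer reports a missing
percentage, never 0 %). Per-layer percentages weighted by counts aggregate
exactly to the global percentage.

The chance-association control mirrors the vasculature channels along the
horizontal in-plane axis — an exact voxel involution — and re-runs the full
association pipeline on the flipped volume (not merely a distance lookup).
On attached scenes the flipped fraction drops; on `placement = "random"`
scenes observed and flipped fractions agree in expectation, which is the
null's calibration. Note that the chance level is not zero: it is the
geometric probability that a random cell body lies within 1 µm of a vessel
wall, which grows with vascular density.

Group comparisons follow a fixed decision rule: Shapiro-Wilk at 0.05 on
each group, then paired/unpaired t-test for two normal groups,
Mann-Whitney otherwise, Kruskal-Wallis for more than two groups; groups
under 3 observations refuse the normality gate and force the
non-parametric branch.

## Electrophysiology

Sweeps are modeled as a single passive RC compartment (justified by the
linear steady-state I–V of these glial cells): resistance `Rm` (MΩ) in
parallel with capacitance `Cm` (pF), resting at `Vrest` (mV). Units are
chosen so that `dV[mV] = I[pA]·Rm[MΩ]·1e-3` and `tau[ms] = Rm·Cm·1e-3`;
for an ohmic cell `Gm[nS]·Rin[MΩ] = 1000`.

* `resting_potential()` averages zero-current baseline samples (segments
  following a command change discard a settling window).
* `input_resistance()` fits steady-state deflection against current over
  the *linear range*: the largest contiguous subset of steps (≥ 3) whose
  fit reaches R² ≥ 0.99, which excludes saturating extremes.
* `resting_conductance()` is ΔI/ΔV for the −10 mV hyperpolarizing step
  from holding, using the terminal 20 % of the step as steady state (the
  source marks the window graphically; 20 % is our convention).
* Capacitance is `tau / Rin`; `tau` comes from the area method
  (`∫(Vss − V)dt / (Vss − V0)`, exact for a single exponential and
  unbiased under zero-mean noise), re-integrated over ~10 time constants
  so the long tail does not accumulate noise. The capacitance estimation
  method was not described for the original recordings; `tau/Rin` is this
  package's convention and is flagged as such.
* All reported voltages are corrected by the −15 mV liquid junction
  potential exactly once; a flag blocks double correction.
* `nernst()` evaluates `E = (RT/zF)·ln([out]/[in])` at the inside
  solution's temperature. The default 306.15 K (33 °C, within the stated
  32 ± 1 °C recording range) together with intracellular K⁺ accounted as
  K-gluconate + KCl only reproduces the published potassium equilibrium
  potentials; both choices are configurable.
* `pca_membrane_props()` runs a standardized-variable PCA of Vm, Gm, Rin
  and Cm (explained variances sum to 4) and summarizes two-group overlap
  by centroid distance versus within-group spread in the PC1–PC2 plane.

## Numerical choices and degenerate inputs

* Otsu thresholds come from a 256-bin histogram; the threshold is the bin
  edge above the between-class-variance maximum.
* An all-zero channel yields an empty mask with a warning, not an error;
  empty masks yield empty networks with a warning.
* A flat line profile (no unique maximum) is an error naming the channel.
* Non-watertight meshes are rejected for contact-area measurement with an
  instruction to re-segment.
* `simulate_phantom()` is deterministic: each stage (network, placement,
  textures, noise) draws from its own sub-seed of `seed`, and the caller's
  RNG state is never disturbed.
* Soma placement enforces a 2 µm clearance between soma surfaces so that
  blurred blobs never merge; placement failure after bounded retries is an
  error reporting the achieved count.

## Problem sizes used in the shipped checks

The acceptance checks run, per execution: three 120×360×360-voxel census
phantoms with 200 somata each (attachment levels 0, 0.17, 0.5); one
high-resolution phantom (0.12 µm in-plane) for the marker-shell distances;
53 flip-null pipelines on ~10^6-voxel volumes (3 attached, 50 random); tube
and Y-junction geometry fixtures; 100 seeded RC simulations; and a pair of
10^6 µm³ demyelination scenes (27 cells/10^6 µm³ baseline, one third
surviving). These sizes were chosen so the whole suite completes in
minutes on a single core while every estimate stays comfortably inside its
statistical tolerance; all of them scale up through `phantom_params()`.

## Known limitations

* Junction recall on dense random networks is limited when a child vessel
  runs inside or parallel to its parent before diverging; junction-exact
  validation uses constructed Y-junctions.
* Fat vessels clipped by the volume boundary fragment into collinear
  edges (a medial-surface ambiguity, not a diameter bias).
* The phantom's marker shells are rotationally uniform; real pericyte
  coverage is patchy, so phantom pericyte distances scatter less than
  tissue measurements.
* The axial PSF (2–3× wider than lateral, as in any confocal) inflates
  peak-to-peak distances for contacts whose line of sight is inclined out
  of the imaging plane, by up to roughly one in-plane voxel at the default
  settings. The ordering of marker distances is unaffected; absolute
  magnitudes are most accurate for in-plane contacts, exactly as with real
  stacks.
* The RC model has no series-resistance term; recovered parameters are
  therefore clean of the bridge-balance ambiguities real recordings face.
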