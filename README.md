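# perivasc

Quantification of perivascular oligodendrocyte–vessel association in
multi-channel 3D fluorescence volumes, with a seeded synthetic-volume
generator providing analytic ground truth, and passive membrane-property
extraction from patch-clamp sweeps.

## The scientific problem

A substantial fraction of mature oligodendrocytes in the adult brain sit
with their cell body directly on the vasculature — mostly on capillaries,
against the vascular basement membrane. Quantifying this requires, per
cell body: the peak-to-peak distance *d* between the cell-channel and
wall-marker-channel fluorescence maxima along a line through the contact
site; classification as vasculature-associated ("vOL") when
*d* ≤ 1 µm; the caliber of the host vessel (capillary < 8 µm,
intermediate 8–15 µm, large > 15 µm, from twice the median centerline
radius within 20 µm of the soma); whether a centerline branch node lies
within reach (bifurcation); the contact area (soma-mesh faces within a
threshold of the vessel surface, soma as primary surface); depth-resolved
counts in 25 µm bins and densities per 10⁶ µm³; and a chance-association
null in which the vasculature channels are mirrored in-plane and the whole
pipeline re-run. The electrophysiology side extracts V<sub>m</sub>,
R<sub>in</sub> (linear-range slope of ΔV vs ΔI), G<sub>m</sub> = ΔI/ΔV
for a −10 mV step, C<sub>m</sub> = τ/R<sub>in</sub>, applies the −15 mV
liquid-junction correction, and computes Nernst equilibrium potentials
E = (RT/zF)·ln([ion]out/[ion]in).

Original tissue stacks are not available, so the package ships a phantom
generator (`simulate_phantom()`) that emulates the imaging: a
capillary-dominated random vessel network, wall-marker shells at
sub-micrometre offsets (pericyte-like 0.5 µm, endothelial-like 0.3 µm,
basement-membrane-like 0.08 µm), membrane-weighted somata with a
controllable attached fraction that wrap onto the vessel wall,
depth-graded myelin texture, PSF blur, and Poisson + Gaussian noise —
with full ground truth for validation. See the vignette
(`vignettes/perivascular-quantification.Rmd`) for the methods in detail.

## Worked example

```r
library(perivasc)

## potassium equilibrium potential of the standard recording solutions
nernst("K", solution(c(K = 140), temperature = 306.15),
            solution(c(K = 3),   temperature = 306.15))
#> [1] -101.39

## a seeded synthetic cortical volume with 17% vessel-attached somata
p  <- phantom_params(seed = 7, n_somata = 50, attached_fraction = 0.17,
                     channels = c("vessel", "soma", "basement"))
ph <- simulate_phantom(p)
an <- analyze_volume(ph$volume)
an
#> <pv_analysis> 50 somata (50 analyzed), 11 vessel edges
#>   vOL fraction: 16%

head(an$records[, c("soma_id", "distance", "is_vol",
                    "vessel_diameter", "vessel_category")])
#>   soma_id distance is_vol vessel_diameter vessel_category
#> 1       1    0.278   TRUE            3.78       capillary
#> 2       2    0.427   TRUE            2.98       capillary
#> 3       3   10.292  FALSE            3.78       capillary
#> 4       4    2.660  FALSE            3.08       capillary
#> 5       5    0.259   TRUE            3.36       capillary
#> 6       6    5.419  FALSE            2.98       capillary

mean(ph$truth$somata$attached)   # generating truth
#> [1] 0.16

## chance-association control: mirror the vasculature, re-run everything
fn <- flip_null(ph$volume)
c(observed = fn$observed, flipped = fn$flipped)
#> observed  flipped
#>     0.16     0.14

## passive membrane properties from simulated sweeps
cc <- simulate_rc_sweeps(12, 62, -71.5, cc_protocol(), noise_sd = 0.3, seed = 1)
vc <- simulate_rc_sweeps(12, 62, -71.5, vc_protocol(holding = -71.5),
                         noise_sd = 3, seed = 2)
correct_ljp(membrane_props(cc, vc))
#> <membrane properties> (LJP-corrected)
#>   Vm    -86.50 mV
#>   Rin    11.99 MOhm
#>   Gm     83.35 nS
#>   Cm     63.38 pF
```

Per record: `distance` is the peak-to-peak distance (µm) to the nearest
wall marker, `is_vol` applies the inclusive 1 µm criterion, and the
diameter/caliber come from the extracted centerline network. In this
scene 8 of 50 somata were generated attached (16 %), and the pipeline
recovers exactly that fraction; the flipped control drops to the chance
level set by the vascular density. The membrane summary reproduces the
generating parameters (R<sub>in</sub> 12 MΩ, C<sub>m</sub> 62 pF,
V<sub>rest</sub> −71.5 mV → −86.5 mV after the −15 mV junction
correction; G<sub>m</sub>·R<sub>in</sub> = 1000 for a passive cell).

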