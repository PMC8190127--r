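---
title: "Models and methods behind chipbarrier"
author: "chipbarrier authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chipbarrier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipbarrier)
```

`chipbarrier` analyses barrier-function experiments run in a
high-throughput bilayer organ-on-chip plate: 96 microfluidic devices, each
made of two stacked 1 mm x ~250 um channels separated by a track-etched
porous membrane (3 um pores, 2e6 pores/cm^2), with endothelial cells and
pericytes cultured on opposite membrane faces. The two channels coincide
over a 3.7 mm^2 overlap region - the only place where the two cell layers
face each other - and every device is serviced through a 2x2 block of
wells on a standard 384-well plate top. This vignette explains the models
the package implements, the choices behind their defaults, and what the
synthetic-data generators do and do not emulate.

## Plate and device model

Devices are addressed `A1`-`H12`; `device_wells()` maps each device to its
four wells (top/bottom channel inlet and outlet). Which well of the 2x2
block serves which port is a plumbing convention that the plate itself
does not disclose, so the package fixes a default (top row of the block =
top channel, left column = inlet) and exposes it as an argument; any
consistent convention yields the same bijection of 96 x 4 roles onto the
384 wells, which is the property the tests pin down.

`device_geometry()` carries the physical constants. Channel height is
nominally "approximately 250 um"; the package takes exactly 250 um by
default and leaves it configurable. Two derived quantities matter
downstream: the channel volume (membrane area x height; 8.5 mm^2 x 250 um
= 2.125 ul, the ~2.1 ul per channel quoted for the platform) and the
membrane porosity (`pi (d/2)^2 rho` = 0.141 for the default pore
specification), which is validated to lie in (0, 1) because a porosity at
or above 1 means physically overlapping pores.

## Shear stress and flow

Wall shear stress in a wide, shallow rectangular channel under laminar
flow follows the parallel-plate relation `tau = 6 mu Q / (w h^2)`. The
package uses this relation - without the finite-aspect-ratio Fourier
correction - because at aspect ratio 4:1 (1 mm x 250 um) the correction is
a few percent, smaller than the uncertainty in medium viscosity, and
because the platform's two published operating points are consistent with
the uncorrected form. Medium viscosity is not a property of the device, so
a default had to be chosen: `MEDIUM_VISCOSITY_PA_S = 6.5e-4` Pa s, a
standard value for serum-supplemented culture medium at 37 C. With that
default the two shear set points 0.01 and 0.5 dyn/cm^2 convert to 1 and
48 ul/min (nearest integer), which is what `scripts/acceptance.R`
recomputes. Users with a measured viscosity should pass it explicitly;
the conversion is linear in `1/mu`, so the sensitivity is easy to reason
about. Pump output is displacement-based: flow = stroke volume x
frequency (`pump_flow_rate()`).

## Permeability

The estimator is the standard endpoint form for two-compartment tracer
assays:

    P = (C(t) - C(t0)) * V / (A * t * C0)     [cm/s]

with receiver concentration `C`, receiver loop volume `V` (cm^3),
exchange area `A` (cm^2), elapsed time `t` (s) and initial donor
concentration `C0`. Three quantities in this equation are not uniquely
pinned down by the assay description, and the package makes each an
explicit argument with a documented default:

* **Area `A`** defaults to the channel-overlap area (3.7 mm^2), because
  outside the overlap the tracer crosses a bare or single-culture
  membrane and the overlap is the only region where both cell layers
  separate the compartments. Normalising to the top-channel membrane area
  (8.5 mm^2) is a defensible alternative (it scales all coefficients by
  3.7/8.5 without affecting comparisons between conditions) and is one
  argument away.
* **Volume `V`** defaults to 100 ul, inside the platform's 60-150 ul
  recirculating range.
* **`t`** is the elapsed time of the chosen endpoint sample, by
  convention the final (260 min) timepoint.

The estimator is exact for the one-way linear-flux model
(`linear_flux_series()`), and that consistency holds for *any* `P`, `A`,
`V`, `C0` and endpoint because the same factors enter the forward model
and the estimator. For the bidirectional two-compartment model
(`simulate_two_compartment()`, solved in closed form because the system
is linear: the concentration difference decays as
`exp(-P A (1/V_t + 1/V_b) t)` with total mass conserved) the endpoint
estimator under-reads the true coefficient by the analytic factor
`(1 - e^{-kT})/(kT)`; the tests assert both this factor and agreement of
the simulator with an independent ODE integration. At the coefficients
the assay actually produces (1e-6 to 1e-5 cm/s) the factor is within a
few percent of 1 at 260 min, which is why the endpoint form is an
acceptable estimator in this regime.

Sampling corrections: each sampling event withdraws 10 ul from each loop.
The default policy assumes replacement with blank medium, so
concentrations scale by `(V - s)/V` at each event and the withdrawn mass
is tracked. Whether the original experiments corrected for sampling is
not recorded; the policy is a simulator option, not part of the
estimator.

Fluorescence calibration is a linear standard curve per tracer molecular
weight (FITC-dextran plate reads are linear over 0-50 ug/mL). The
table-driven pipeline (`permeability_from_readings()`) converts readings
with the *unclipped* inverse of the curve before differencing: the fitted
intercept then cancels exactly in `C(t) - C(t0)`, which matters because
receiver concentrations are small compared to the standard range and an
intercept error would otherwise dominate.

## Image quantification

The pipeline mirrors a connected-component approach to device tiles:

1. **Edge cleaning** (`clean_channel_edges()`). Laser-cut channel walls
   leave near-saturating ridges in the junction-stain channel. Candidate
   pixels are those whose green-minus-blue brightness difference exceeds
   6 MADs of that difference over the tile; candidates are split into two
   classes by an automatic histogram threshold and the upper class is
   zeroed only if the class separation exceeds 40 percent of the tile's
   brightness-difference range. On artifact-free tiles the candidate set
   is just the brightest cellular signal, the separation test fails and
   the tile passes through bit-identical. The decision uses only
   relative quantities, so rescaling intensities does not change which
   pixels are suppressed. Zeroed seams also disconnect the overlap region
   from the flanking channel segments, which is what makes the next step
   work.
2. **Overlap isolation** (`extract_overlap_mask()`). The combined
   nuclei + junction brightness is thresholded (Otsu; a half-threshold
   retry covers the case where Otsu locks onto the cells instead of the
   channel background), components are labelled, and a series of
   decisions discards non-overlap components: more than 30 percent of
   pixels within 3 px of the tile border, or area outside
   3.7 mm^2 +/- 40 percent; among survivors the component nearest the
   image centre wins and is morphologically closed (40 um radius) and
   hole-filled. Finally the mask must contain cell signal - the 99th
   percentile minus the median of combined brightness over the eroded
   interior must exceed 0.12 - otherwise a "no cells detected" error is
   raised, which plate reports translate to ND. A cell-free device still
   shows an autofluorescent overlap rectangle, so ND detection must come
   from absent cell texture, not absent geometry.
3. **Coverage** (`ec_coverage()`). The junction channel is thresholded
   within the mask and positive pixels divided by mask pixels. Automatic
   thresholds are meaningless when the within-mask histogram is not
   bimodal, so the threshold state machine distinguishes three cases: no
   foreground/background structure (class separation below 3x the class
   spreads), a clean split (near-empty histogram valley at the
   threshold), and saturation (structure without a valley, i.e. the
   split separates stain texture rather than covered from uncovered).
   Uniform regions are intrinsically ambiguous - a dim empty rectangle
   and a bright confluent one differ only by a scale factor - so the DNA
   channel arbitrates: nuclei present means confluent (coverage 1),
   absent means cell-free (coverage 0). In mono-culture mode, where
   junctional staining is weak, nuclear objects are additionally
   segmented, dilated by 5 um (bridging the gap between nucleus and
   border stain) and unioned with the positive set.
4. **Counting** (`count_nuclei()`). Components of the thresholded DNA
   channel below 20 um^2 are discarded as debris; the singleton nucleus
   area is estimated as the median component area and each component
   counts as `round(area / singleton)` with minimum 1. This area-ratio
   rule handles touching clusters without watershed splitting and is
   robust to occasional accidental contacts, since a merged pair simply
   counts as 2. Viability applies the same segmentation to the live and
   dead channels and reports `live / (live + dead)`.

Determinism: identical input and configuration give identical output (no
randomness anywhere in the pipeline). Scale equivariance holds to the
resolution of the 256-bin threshold histograms; masks recovered from
rescaled tiles agree to IoU > 0.99 rather than bit-for-bit.

## Immunoassay calibration and qPCR

The 5-PL model `F(x) = d + (a - d)/(1 + (x/c)^b)^g` is fitted by
Levenberg-Marquardt with residuals weighted by the predicted response,
matching the multiplicative (constant-CV) noise of bead-based readers.
`c` and `g` are fitted on the log scale; `g` is constrained to
[0.25, 4]. That constraint deserves a note: the 5-PL family has a
near-flat likelihood ridge along which `g` grows without bound while `c`
compensates, leaving the curve (and therefore every recovered sample
concentration) essentially unchanged. The raw `c` of an individual fit is
consequently heavy-tailed under noise even though the curve is stable; the
identifiable dose-scale summary is the midpoint concentration
`c (2^{1/g} - 1)^{1/b}`, which `fit_5pl()` reports as an attribute. The
test suite judges calibration of the fitted scale on the replicate median
of `c` and the mean of the midpoint, not on single fits. Inversion is
closed-form; responses outside the open asymptote range are flagged
`below`/`above` rather than thrown, and below-range samples are a QC
decision left to the caller.

Comparative-CT fold changes follow the standard two-step:
`dCt = Ct(gene) - Ct(reference)` per sample (GAPDH by default), then
`ddCt = mean dCt(condition) - mean dCt(calibrator)` and fold
`2^{-ddCt}`. The condition-mean aggregation is the default; a
per-replicate variant gives the same fold on balanced data plus a usable
spread. Shifting every Ct by a constant leaves folds unchanged, which the
tests assert exactly.

## Statistics

`grubbs_outlier()` implements the two-sided single-outlier screen with
the t-quantile critical value; at most one value is flagged per call, and
a zero-variance sample has no outliers by definition. The critical value
is cross-checked in the tests against a 20,000-replicate null simulation.
`pairwise_welch()` wraps the two-sided two-sample t test; the
unequal-variance Welch form is the default because the variance
assumption behind the pooled form is rarely defensible for plate data,
with the pooled option available. Star annotations follow the
`*`/`**`/`***`/`****` convention at 0.05/0.01/0.001/0.0001. Nominal size
is verified by a 10,000-replicate null simulation. Factorial ANOVA with
post-hoc testing is deliberately out of scope; the package's reports are
per-pair.

## Synthetic data: what it emulates, and what it does not

`render_device_tile()` draws, at 2.6 um/px on an 896 x 1792 tile (a
2x-binned 10x tile scan; chosen so the full 4.66 x 2.33 mm field contains
the 3.7 mm^2 overlap with margins), the structures the pipeline keys on:
channel bands with per-layer autofluorescence, the coincident-segment
overlap, wall-ridge artifacts, a linear illumination gradient, Gaussian
sensor noise, a covered region carved out of a smoothed random field at a
pixel-exact target fraction, soft-edged elliptical nuclei (touching pairs
with probability 0.15 per placement event), ring-shaped junctional
staining plus a diffuse membrane component over the covered area, and
live/dead channels at an exact live fraction. Ground truth (mask,
coverage, count, viability) is bookkeeping, not estimation. Default
nucleus numbers correspond to confluent-monolayer densities of several
hundred to a thousand cells per mm^2 of covered area.

What it does not emulate: point-spread blur and defocus, stitching seams
between tiles, uneven staining batches, nuclear debris and apoptotic
fragments, overlapping cell layers in z, and pericyte signal bleeding
into the endothelial channel. Passing the recovery sweeps therefore shows
that the pipeline's decisions are correct for images with the assumed
structure, not that the pipeline is validated for arbitrary real
micrographs; on real data the thresholds exposed as arguments (cleaning
multiple, area band, debris floor, dilation radius) are the knobs a user
should revisit.

The assay generators mirror the study designs directly: tracer assays at
50 ug/mL load, sampling at 0/20/40/60/120/260 min, 9 replicates per
condition, 2 percent reading noise, and true coefficients set to the
reported condition means; immunoassay tables with a 12-plex panel, 5-PL
truth curves and 5 percent CV; Ct tables with a GAPDH reference,
100-fold channel enrichment of cell-type transcripts and 0.15-cycle
replicate noise (n = 3). The tracer generator defaults to the one-way
flux model, matching the estimator's own model so that the no-noise
pipeline is exactly self-consistent; the bidirectional simulator is the
option to use when studying estimator bias itself.

## Problem sizes and numerical notes

The test suite exercises full-size tiles only in the recovery sweep
(coverage 0.3/0.6/0.9 x two nucleus densities x five seeds, plus three
viability tiles); all other image tests run on a reduced 448 x 896 px
geometry with a 0.8 mm^2 overlap that preserves every pixel-scale
parameter. Monte-Carlo calibrations use 10,000 null replicates for test
size, 1,000 parameter draws for the 5-PL inverse, and 100 replicates for
5-PL fit calibration. Histogram thresholds use 256 bins (64 for the
valley diagnostic); the 5-PL optimiser runs at most 300
Levenberg-Marquardt iterations from data-driven starts. Seeded helpers
save and restore the caller's RNG state, so generators do not perturb
user code.

## Known limitations

* The device-well quadrant convention and the exact component-discard
  decisions of the original image code are reconstructions; both are
  configurable and validated only against the synthetic ground truth.
* The endpoint permeability estimator inherits the one-way assumption;
  at coefficients above ~1e-4 cm/s or times well beyond 260 min the
  bidirectional correction becomes material.
* Below-range immunoassay handling (LLOQ/2 substitution versus flagging)
  is a reporting decision the package surfaces but does not impose.
* Blank devices bearing wall-ridge artifacts cannot have those artifacts
  cleaned (there is no cellular class to separate them from); they are
  instead rejected as ND at mask extraction, which is the correct
  plate-level outcome.
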