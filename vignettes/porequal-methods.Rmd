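---
title: "Quantifying resolution and SNR in nanoCT volumes of porous scaffolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying resolution and SNR in nanoCT volumes of porous scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porequal)
```

## The problem

Synchrotron nanoCT of bone-scaffold biomaterials produces reconstructed
volumes whose quality must be compared across acquisition configurations
(camera, X-ray energy, projection count). Two classic figures of merit —
spatial resolution and signal-to-noise ratio — are hard to measure directly
in such samples: the mineralized tissue has intrinsically variable gray
values, and local-tomography acquisition leaves a slow drift of up to ~20%
of the gray level across the analyzed volume. Both effects would contaminate
any global estimate.

The approach implemented here side-steps both problems by measuring quality
only inside and around *closed pores*: air-filled voids in the ceramic
scaffold that are disconnected from the main pore space, contain no tissue
or embedding medium, and appear as bright, roughly spherical objects against
a uniform scaffold background. Every metric is computed per pore and then
aggregated, so no operator input (line placement, ROI drawing) is involved.

Three aligned datasets drive the evaluation, mirroring common practice:

* the raw floating-point reconstruction (the gray values all statistics are
  computed on),
* a binary segmentation of the pore space,
* a label volume in which each isolated pore has a unique id.

For real data the segmentations are supplied by the user (any external
workflow works — the package only fixes the metric definitions); for
validation the phantom generator provides them as ground truth.

## Pore selection

Connected components of the pore mask (26-connectivity by default) are
labeled; every component touching the volume boundary is treated as main
pore space and discarded, as is — when a tissue mask is available — every
component whose one-voxel dilation touches mineralized tissue. Each
remaining pore gets a voxel count, a volume $V$, a triangulated-isosurface
area $A$, and the sphericity shape factor

$$S = \frac{A}{(36\,\pi V^2)^{1/3}},$$

which is scale-free, equals 1 for a perfect sphere and grows with
irregularity. Only pores with **more than 1000 voxels** and **$S < 1.3$**
(both strict) enter the analysis; this removes segmentation artifacts and
fused pores.

### Surface-area estimator

$A$ is measured on a marching-tetrahedra triangulation of the 0.5 level set
of the pore indicator, after smoothing the indicator with a small Gaussian
(σ = 0.8 voxel, configurable). Meshing a *raw* binary field overestimates a
sphere's area by ~9% (staircase facets), and plain face counting by ~50%;
with the default smoothing the estimate is within ~1% for spheres of radius
≥ 10 voxels and within ~2% for spheroids, which is what closed pores look
like. The price is a downward bias on sharp-edged objects (a cube's edges
are rounded over ~2σ), acceptable here because the filter explicitly
excludes irregular shapes. The same estimator is used for pore shapes and
for scaffold morphometry, so surfaces are comparable across the package.

## Resolution: the edge-spread step-up curve

For each pore, every voxel is assigned a signed Euclidean distance to the
pore surface: surface voxels are pore voxels with a 6-neighbour outside the
mask; distances are positive inside, negative outside. One-voxel shells
$[k-0.5, k+0.5)$ then bin the raw gray values, and the shell means form a
sigmoid "step-up" curve from the scaffold plateau to the pore plateau.
Outside shells are restricted to scaffold voxels away from the blur halo of
any other pore, so neighbouring features cannot distort the outer plateau.

If the interface is modeled as an ideal step convolved with a Gaussian of
width $\sigma$, the curve is an error function,

$$f(d) = A_1 + \frac{A_2 - A_1}{2}\left[1 +
  \operatorname{erf}\!\left(\frac{d - x_0}{\sqrt{2}\sigma}\right)\right],$$

fitted per pore by Levenberg–Marquardt least squares (shells weighted
equally; voxel-count weighting is available). The resolution figure of merit
is the FWHM of the blurring Gaussian. It is read off the *measured* curve as
the distance between its crossings with

$$L_1 = A_1 + c\,(A_2 - A_1), \qquad L_2 = A_1 + (1 - c)(A_2 - A_1),
\qquad c = \tfrac{1}{2}\left[1 - \operatorname{erf}\sqrt{\ln 2}\right]
\approx 0.1195,$$

the levels at which the ideal step brackets the half-maximum points of the
blurring Gaussian; the model-implied value $2\sqrt{2\ln 2}\,\sigma_{fit}$ is
reported alongside as a cross-check. The constant $c$ is configurable for
sensitivity analyses.

Numerical details that matter:

* **Crossing location.** Brackets are found linearly between shell centers;
  the crossing is then refined on a monotone Hermite interpolant of the
  neighbouring shells. Plain linear interpolation on the convex erf tail
  overshoots each crossing, inflating the FWHM by ~3% at unit shell
  spacing; the refinement brings exact-model profiles within 1% and falls
  back to the linear estimate whenever noise breaks the local bracket.
  Multiple crossings (noise) are resolved by taking the pair bracketing the
  fitted edge center $x_0$.
* **Shell range.** 10 voxels outside; inside, the smaller of 10 voxels and
  the pore's inscribed radius, so the inner plateau is never contaminated by
  the opposite interface.
* **Failure modes.** A plateau contrast below a configurable floor raises a
  "no contrast" failure; non-convergence or a missing level crossing flags
  the pore, which is excluded from resolution statistics but keeps its SNR
  if that is valid.
* **Known bias.** Distances are measured to the *voxelized* segmented
  surface, whose bumpiness systematically narrows the apparent transition:
  on blurred digitized spheres of radius 9–12 voxels the recovered width
  is ~4–7% below truth even without noise (the continuum radial profile
  fits 2–3% *above*). The estimates are therefore conservative, which is
  acceptable for comparing configurations measured the same way.

## SNR on eroded regions

Blur contaminates voxels near the interface, so both the pore and the
surrounding scaffold are eroded with a spherical structuring element of
radius 5 voxels (the inclusive digital ball, implemented exactly via the
squared Euclidean distance transform). The per-pore SNR is

$$\mathrm{SNR} = \frac{\mu_{pore} - \mu_{scaffold}}
  {\max(\sigma_{pore}, \sigma_{scaffold})},$$

with means and standard deviations taken over the eroded regions in the raw
volume. Pores with **no more than 100 voxels** remaining after erosion are
excluded. A noiseless (zero-SD) region yields an infinite sentinel and is
excluded from aggregation rather than raising an error.

Because of the slow gray drift, the scaffold statistics are local by
default: for each pore, only eroded scaffold voxels within 15 voxels of
that pore's surface are used. A global-scaffold mode is selectable; with a
20% drift the global SD conflates drift with noise, while the local shell
keeps per-pore SNR within a few percent of its drift-free value (the
matched-seed phantom test quantifies this). Whether the original workflow
used a local or global scaffold region is not documented; both are exposed.

Aggregation reports the sample mean and the $n-1$ standard deviation of SNR
and resolution over valid pores, plus the pore count — the same summary
shape used to compare scan configurations.

## The phantom generator

The generator produces the validation conditions, not a tunable benchmark:
a solid scaffold at gray level 100 containing bright closed pores at gray
level 200, an optional pore-level channel touching one face (so the
isolated/main distinction is exercised), an optional tissue layer on the
channel wall, a multiplicative low-order polynomial drift field whose span
is a stated fraction of the scaffold level, isotropic Gaussian blur of known
σ (kernel truncated at 3σ), and i.i.d. Gaussian noise added after blurring
(reconstruction-domain noise; the true noise model of a reconstruction
pipeline is correlated, see limitations).

Defaults are the study conditions used throughout the tests: a 200³ grid at
50 nm voxels with 35 pores of radius 9–11 voxels, blur σ = 2 voxels, noise
σ = 10 gray units (true SNR 10), drift 0. The radii are chosen so that
every pore passes the 1000-voxel filter, keeps well over 100 voxels after
the radius-5 erosion, and satisfies $r/\sigma \ge 3$, where the
sphere-curvature bias of the erf fit stays within ~5%. Placement is seeded
rejection sampling with a guaranteed pairwise surface separation of at
least twice the blur support radius; at these densities the placement sits
comfortably below the random-packing jamming limit, and the drift
coefficients are drawn before placement and noise so that runs differing
only in drift amplitude share geometry and noise exactly (enabling
matched-pair tests). Ground truth (labels, centers, radii, true FWHM
$= 2\sqrt{2\ln2}\,\sigma\,\cdot$ voxel size, true SNR = contrast/noise σ) is
a pure function of the spec.

What the phantom does *not* emulate: correlated reconstruction noise, ring
artifacts, phase-retrieval fringes, partial-volume texture of real
ceramics, non-spherical pore shapes, and intensity-dependent noise. Passing
the recovery tests therefore demonstrates correctness of the estimators
under the stated model, not robustness to every real-data artifact.

On phantom input the pipeline uses the generator's ground-truth
segmentation by default, mirroring the intended use where segmentation
comes from an external (typically semi-automatic) workflow. Threshold/Otsu
re-segmentation is available and is exercised in tests at noise levels
where a plain threshold is sound; at very low SNR a plain threshold leaves
noise holes inside pores and the radius-5 erosion then empties them — a
physical limitation of thresholding, not of the metrics.

## Morphometry

A two-threshold segmentation yields a three-phase map (pore / scaffold /
mineralized tissue; the threshold-to-phase mapping is configurable since
brightness ordering depends on the reconstruction convention). The package
reports per-phase volumes; scaffold surface area with and without closed
porosity (cavities enclosed by the scaffold are filled before meshing when
excluded); the specific surface area (per bulk volume) and the
surface-to-volume ratio (per phase volume) — both normalizations are
emitted because published values do not always state which was used; and
the fraction of the *available* scaffold surface covered by mineralized
tissue. Coverage is counted on voxel faces (6-adjacency) rather than on the
mesh: contact is a topological question and face counting is robust; the
mesh is used only for areas. "Available" excludes closed-porosity walls
(tissue cannot reach them) and faces on the volume boundary, which are
truncation artifacts of local tomography and are excluded from all surface
estimates.

## Reproducibility and problem sizes

Every random quantity (phantom placement, drift field, noise) flows from a
single integer seed; identical configs give bit-identical volumes and
output tables. The validation suite runs three blur settings
(σ ∈ {1.5, 2, 3}) and two noise settings (true SNR ∈ {4, 8}) at the full
200³ study conditions, each with 35 valid pores, plus a matched-seed drift
pair; exact-oracle checks (brute-force erosion, all-pairs signed distance)
run on instances up to 24³, where exhaustive computation is cheap. Module
tests use smaller phantoms (96³–150³) for speed.

## Limitations

* The resolution estimate is conservative (see the voxelized-surface bias
  above) and depends mildly on pore curvature; comparisons are meaningful
  between datasets measured identically, which is the intended use.
* The erf model assumes a Gaussian blur kernel; strongly non-Gaussian point
  spread (e.g. phase-contrast fringes) will fit poorly and should show up
  in the per-pore RMSE diagnostics.
* Sphericity and surface areas inherit the smoothing-based estimator's
  small-object bias; values for objects under ~8 voxels radius should not
  be over-interpreted (the 1000-voxel filter removes most of them).
* The semi-automatic segmentation that produced the original labeled
  datasets is not reproduced; segmentation is pluggable instead.
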