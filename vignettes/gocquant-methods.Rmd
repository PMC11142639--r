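---
title: "Quantifying transzonal projections: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transzonal projections: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gocquant)
```

## The measurement problem

During oocyte growth, granulosa cells contact the oocyte through
transzonal projections (TZPs): thin, filopodium-like processes that cross
the zona pellucida (a glycoprotein coat roughly 7 µm thick in the mouse)
and attach to the oocyte surface. Experiments that perturb granulosa-cell
signalling are read out through a battery of image-derived quantities:

* how many TZPs cross the zona in an equatorial confocal section,
  normalized to the oocyte diameter;
* the 3D morphometry of individual granulosa cells (volume, surface area,
  sphericity) and of individually traced TZPs (arc length, mean width);
* the *trajectory* of each TZP, summarized by the orientation statistic
  Δ = d(origin) − d(tip), where d(·) is the distance to the oocyte
  surface — Δ > 0 means the tip is closer to the oocyte than the origin
  ("toward"), Δ < 0 means it points away;
* gap-junctional coupling, measured as the final/pre-bleach fluorescence
  ratio of the oocyte after repeated photobleaching (FRAP);
* proliferation (EdU-labelled fraction), relative mRNA abundance
  (2^−ΔΔCt against *Rpl19*), and two-group contrasts summarized as
  mean ± SEM, percent change and one- or two-sample two-tailed t-tests.

`gocquant` implements these computations as composable functions and
validates them against a synthetic ground-truth generator, because the
original raw image stacks behind such studies are typically not
deposited — only derived measurements are. Everything the package claims
is therefore demonstrated on data whose truth is known exactly.

## The equatorial counting rule

The mid-zona circle of radius $r_{oocyte} + t_{zona}/2$ is sampled by
bilinear interpolation at uniform arc steps (default: one pixel of arc).
A sample $i$ is counted as a TZP iff

$$s_i > b \quad\text{and}\quad s_i > s_{i-1} \quad\text{and}\quad s_i > s_{i+1},$$

with circular neighbour indexing (the drawn circle is closed) and $b$ the
background level of the oocyte cytoplasm. Three choices deserve note:

* **Strict inequalities.** A plateau of equal neighbouring samples is not
  counted. This is the literal reading of "higher than each of its
  immediately neighbouring points"; in continuous noisy data ties have
  measure zero, and on synthetic noiseless data the strictness is what
  keeps a flat zona baseline from generating spurious peaks (bilinear
  interpolation of a constant region is constant, so equality fails the
  test everywhere).
* **Background estimator.** The cytoplasm level is the median (optionally
  mean) over an interior disk of radius 0.7 × the oocyte radius — inside
  the bright F-actin cortex, robust to organellar texture.
* **Smoothing.** No smoothing is applied by default; noiseless profiles
  need none and the raw rule is the reference behaviour. For noisy data a
  circular boxcar of 3 samples (about the arc width of a 0.4 µm filament
  at 0.1 µm sampling) is the recommended setting: wider windows merge
  adjacent peaks, narrower ones let read noise split the flat top of a
  bump into two local maxima. The choice is an explicit argument
  (`smooth_window`), never implicit.

The count is reported raw and normalized to the oocyte diameter
(counts/µm). By construction a circular profile of $n$ samples can hold
at most $\lfloor n/2 \rfloor$ strict local maxima.

## 3D morphometry

**Segmentation.** Membrane-labelled cells are recovered by thresholding
the membrane channel, flood-filling any enclosed interior (non-membrane
regions not connected to the volume border), and labelling 6-connected
components. Components with volume strictly below 100 µm³ are discarded —
an exclusive filter, so a cell measuring exactly the cutoff survives.
The published unit for this filter is µm², which we read as a volume in
µm³ (a volume filter with an area unit is taken to be a typo); the
threshold is configurable. Touching cells merge into one label; the
generator never places cells in contact, and real data would need the
manual split/merge editing that is out of scope here.

**Volume, area, sphericity.** Volume is voxel count × voxel volume.
Surface area comes from a marching-tetrahedra iso-surface (iso-level 0.5)
of the binary mask after mollification with a 3³ box kernel. The
mollification matters: meshing the raw binary indicator quantizes surface
normals and overestimates a digitized sphere's area by ~28%, while naive
voxel-face counting is worse still; after mollification the sphere error
is ~+0.6%. Sphericity is the Wadell ratio
$\Psi = \pi^{1/3}(6V)^{2/3}/A$ — 1 for a sphere, $(\pi/6)^{1/3} \approx
0.806$ for a cube — and discretization can push near-spheres a few
percent above 1.

**Filaments.** TZP traces enter as SWC polylines (the established
polyline-plus-radius tracing exchange format); tracing itself — a
semi-automated, proprietary-tool workflow — is not re-implemented, the
measurements are. Length is polyline arc length; width is the mean of
per-point diameters floored at 0.1 µm (the tracing minimum); spot
discretization places points at arc-length multiples of the spot spacing
(default 0.2 µm, the acquisition z-step), always including start and tip.
Distance to the oocyte uses a sphere model (signed: negative inside),
fitted by least squares when not supplied; every TZP spot lies outside
the oocyte, so the sign convention only matters for degenerate synthetic
input. Δ = 0 ("neutral") is reported as its own class and kept in the
denominator of the per-cell away-proportion; cells with no filaments
report missing proportions rather than 0.

## FRAP model

The coupling statistic is the final/pre-bleach oocyte fluorescence ratio.
For validation the package simulates a two-compartment exchange: after a
bleach removing fraction $b$ of the oocyte signal, recovery from a large
granulosa reservoir at rate $k$ gives the normalized curve
$R(t) = 1 - b\,e^{-kt}$, sampled at the acquisition times (after the
10th … 60th bleach, i.e. 10–60 s). $k = 0$ leaves $R = 1 - b$; large $k$
drives $R \to 1$; $R$ is monotone in $k$. The published description of a
second, size-correcting normalization is not a well-formed formula; the
package implements one explicit reading
($[F_{gran}(t)/F_{gran}(pre)]/[F_{ooc}(t)/F_{ooc}(pre)]$) as
`double_normalized`, flagged experimental, and keeps the oocyte ratio as
the primary statistic. Per-iteration bleach physics is collapsed to the
recorded timestamps. The exchange rate is identifiable by nonlinear least
squares on the normalized curve; on noiseless curves the generating $k$
is recovered to numerical precision.

## Statistics

Percent change is $100\,(\bar{x}_{ref} - \bar{x}_{test})/\bar{x}_{ref}$,
positive for reductions — matching how group differences are phrased
("25% decrease"). SEM uses the sample standard deviation; $n = 1$ yields
a missing SEM, never 0. The two-sample test defaults to Student's
pooled-variance t (the common default of the graphing software such
studies use), with Welch behind a flag; one-sample tests serve
normalized ratios against 1. The degenerate zero-variance-equal-means
case is defined as $t = 0, p = 1$. 2^−ΔΔCt normalizes each sample's gene
Ct to its *Rpl19* Ct and to the calibrator-group mean ΔCt, so calibrator
fold changes have geometric mean 1. No multiple-testing correction is
applied, matching the analysis the pipeline reproduces.

## What the generator does and does not emulate

The synthetic scene is an anti-aliased raster of: an oocyte disk/sphere
(radius 30 µm by default) with cytoplasm signal and a bright cortical
ring; a zona annulus/shell (7 µm) with faint matrix signal; TZPs rendered
as capsules — segments with a Gaussian cross-section of σ = width/2,
max-blended so each filament peaks at exactly `tzp_intensity`; in 3D,
ellipsoidal membrane-labelled cell bodies outside the zona with
soft-edged shells whose half-maximum sits exactly on the nominal outer
surface (the ground-truth cell volume is defined at that outer surface,
which is what a half-maximum threshold recovers). Filament polylines grow
from the oocyte-facing surface point of each cell, toward the oocyte (or
away, for a configurable fraction), with tortuosity as a seeded
small-angle random walk. Noise is Gaussian read noise, optionally
preceded by Poisson shot noise. Pixels are 0.1 µm in 2D and
0.1 × 0.1 × 0.2 µm (x, y, z) in 3D, with coarser grids used in tests for
speed. TZP angular positions are jittered regular spacings, which bounds
the minimum peak separation; surface density and angular distribution are
free parameters, not biological claims.

Deliberately not modelled: the optical PSF, photobleaching during
acquisition, nuclear/DAPI textures, vesicle-laden cytoplasm texture,
cell-cell contact, and tracing errors. Passing the ground-truth-recovery
suites therefore shows the *measurement* code is correct, not that the
upstream segmentation/tracing of real micrographs would be error-free.

In the two-group simulator, per-cell TZP counts are Poisson around the
group mean, cell volumes lognormal (CV 0.5 around a 323.2 µm³ control
mean), and TZP lengths truncated-normal around 4.6 ± 0.8 µm — the control
means match the published control groups, and Poisson is the minimal
dispersion model for counts in the absence of a published per-cell
dispersion estimate. Treated-group means are control means scaled by
(1 + effect). Per-specimen seeds derive deterministically from one master
seed, so experiments are exactly reproducible.

## Problem sizes and numerical tolerances

The validation suites run at sizes chosen to keep the whole test suite in
the low minutes on a single core while staying in the regime the defaults
describe: 1024² pixels (0.1 µm) for full-size equatorial images, 448²
for unit tests of the same code path; 3D scenes of a few hundred
thousand voxels at 0.25–0.3 µm; 20 seeds for noisy counting; 100
replicate experiments at n = 25 cells/group for the end-to-end effect
recovery; 10,000 replicates for null p-value uniformity. Tolerances:
noiseless counting is exact; noisy counting is held to ≤5% mean count
error at noise of 20% of contrast; digitized-sphere sphericity to 3%;
segmentation volume recovery to 5%; FRAP closed-form agreement to 1e−9
and rate recovery to 1%; |Δ| ≤ L to 1e−9 absolute slack.

## Known limitations

* Touching cells are not split; segmentation is validated on separated
  bodies only.
* The "segmented circle" of the counting protocol is idealized as a true
  circle; manually traced polygonal circles are not supported.
* The sphere model of the oocyte surface ignores local surface
  indentations; a mesh-distance option would be needed for strongly
  non-spherical oocytes.
* TIFF calibration is carried in a JSON sidecar rather than TIFF tags;
  images from other tools need an explicit `pixel_size`/`voxel_size`.
* Attribution of equatorial peaks to individual cells is out of scope, as
  it is for the protocol the package implements.
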