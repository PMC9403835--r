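---
title: "Observer-independent cytoarchitectonic border detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Observer-independent cytoarchitectonic border detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoborder)
```

This vignette documents the scientific model behind `cytoborder`, the
parameters that matter, the synthetic data the package is calibrated on,
and the design decisions taken where the underlying methodology leaves
room for interpretation.

## The problem

Cortical areas differ in cytoarchitecture: the size, packing density and
laminar arrangement of neuronal cell bodies across the six cortical
layers. Classical parcellations drew areal borders by visual inspection,
which is observer-dependent and hard to reproduce. The quantitative
alternative implemented here treats the laminar cell-body distribution as
a statistical signal: borders are positions where the shape of the laminar
density profile changes significantly, tested with a multivariate
statistic rather than judged by eye.

## From image to GLI profile

**Gray level index.** A cell-body-stained section is binarized (cells are
dark; the default is Otsu's threshold, computed with `EBImage`) and tiled
into non-overlapping measuring fields of `field_size_px = 16` pixels at a
nominal pixel size of 1.02 µm. The foreground fraction of a field is the
GLI, an estimator of the local volume fraction of cell bodies. GLI values
are kept as fractions in [0, 1] throughout. Fields are non-overlapping and
trailing partial fields are discarded — the simplest contract consistent
with a "measuring field"; the exact in-house binarization used on real
Merker-stained material is unpublished, and any constant offset between a
reimplementation and the original is irrelevant to border statistics,
which only compare profiles with each other.

**Traverses.** Profiles must run perpendicular to the cortical layers. The
package solves the Laplace equation on the ribbon between the outer
(layer I/II) and inner (layer VI/white matter) contours, with Dirichlet
values 0 and 1 on the rasterized contours and reflecting (zero-flux)
conditions on the lateral open ends of a region of interest — the
reflecting ends avoid artificial field distortion at the cut lines. The
solver is red-black successive over-relaxation (`omega = 1.9`) on a
regular grid (`grid_res_um = 5` by default; the annulus closed form in the
test suite bounds the discretization error at ~1–2 % for ribbons a few
dozen cells thick). Traverses are seeded at equal arc-length spacing on
the outer contour and integrate the normalized gradient of the potential
with a fixed-step midpoint scheme (step = half a grid cell), terminating
at φ ≥ 0.999 with the final step clipped to the crossing by bisection.
Traverses whose gradient vanishes or that exit the ribbon are excluded
with a warning and the remainder re-indexed consecutively, so profile
indices stay gap-free.

**Profiles and features.** GLI is sampled by bilinear interpolation at
`n_points = 101` equidistant arc-length positions along each traverse
(0–100 % cortical depth inclusive; the methodology prescribes only the
normalization to 100 %, the grid density is a package choice). Each
profile is summarized by 10 features: the mean amplitude plus the
depth-weighted centre of gravity, SD, skewness and kurtosis of the profile
and of its absolute first derivative (central differences, one-sided at
the ends). Moments are weighted by the profile values — the profile is
treated as a frequency distribution over depth, which is the only reading
under which "cortical depth of the centre of gravity" is meaningful.
Whether the original methodology uses |y′| or signed y′ for the derivative
moments is not documented; both are available
(`profile_features(derivative = )`), absolute is the default. Before
distance computation the features are z-scored across the section's
profile set: the features carry incommensurate units and small-block
covariance pooling alone does not remove cross-feature scale pathologies.

## Border detection

Blocks of `b` adjacent profiles (12–30 in standard runs) slide along the
ribbon. At each position the squared Mahalanobis distance between the
block mean feature vectors, with the pooled sample covariance, is
converted to Hotelling's T² and an F statistic on (10, 2b − 11) degrees of
freedom. Three acceptance layers then control false positives:

1. **Bonferroni within block size.** "Bonferroni-corrected α = 0.001" is
   read conservatively as the family-wise level per block size, divided by
   the number of tested positions. (Whether the original divisor also
   includes the number of block sizes is unknown and not assumed.)
2. **Consensus across block sizes.** Significant strict local maxima of D²
   (window half-width `w = 2`; plateaus count once, leftmost index — the
   numerical definition of "local maximum" is a package choice) are
   clustered across block sizes by single linkage with a tolerance of 4
   profiles; a border needs ≥ 3 distinct supporting block sizes, and its
   consensus position is the cluster median.
3. **Reproducibility across sections.** Consensus candidates are chained
   across *adjacent* serial sections (a missing section breaks the chain —
   the stricter reading of "adjacent") with the same positional tolerance;
   chains spanning ≥ 3 sections are accepted.

Near-singular pooled covariances at small block sizes are shrunk toward
their diagonal, with the smallest λ ∈ {0, 10⁻⁴, 10⁻³, 10⁻²} that brings
the condition number below 10⁸; the λ used is recorded in the output.
The documented block-size range is itself ambiguous in the source
literature (text: 12–30; the illustrative figure caption: 20–30); the
range is a parameter, default 12–30.

## Atlas maps, volumetry, statistics

Probability maps are voxelwise subject-overlap fractions (exact multiples
of 1/N); the maximum probability map assigns each voxel to the area of
highest probability, with a documented two-stage tie rule: higher mean
probability over the 26-neighborhood, then lower area id, with tie counts
reported. The published refinements of MPM construction (e.g. logic for
voxels below an overlap threshold) are not reproduced. World coordinates
use mm = (0-based voxel index + 0.5) × voxel size.

Volumes use the Cavalieri estimator (section spacing default 1.2 mm,
i.e. at least every 60th 20-µm section) scaled by the per-brain shrinkage
factor fresh/processed volume. The split-plot ANOVA (within: area,
hemisphere; between: sex) is fitted with `stats::aov` error strata
`Error(brain/(area*hemisphere))`; partial η² is SS_effect/(SS_effect +
SS_error-of-stratum). No sphericity correction is applied by default (the
design this mirrors reported sphericity as satisfied). Whether "whole
brain volume" for normalization means the fresh MRI volume or the
histological volume is unspecified in the source; the cohort generator
carries both so either can be used.

Hierarchical clustering of areal feature vectors uses Euclidean distance
with Ward linkage via `stats::hclust`; distances are fed as squared
Euclidean / 2 so that reported heights equal the Ward merge cost (the
increase in within-cluster sum of squares) — conventions differ between
packages, so the package fixes and documents one. Features are z-scored
before clustering by default. The canonical discriminant projection is the
eigendecomposition of W⁻¹B with the same diagonal-shrinkage path as the
Mahalanobis machinery; it is descriptive (projection and centroids), and
no classification accuracy is claimed.

## The synthetic data, and what it does not show

No raw histology of the mapped region is publicly deposited, so the
package ships generators at two levels.

**Raster level.** `render_section()` draws a folded or flat cortical
ribbon at a configurable pixel size with cell bodies as anti-aliased dark
disks (intensity 0.1 on a 0.9 background, additive Gaussian noise
σ = 0.02) placed by an inhomogeneous Poisson process. Under this Boolean
model the intensity is λ(x) = −log(1 − f(x))/E[disk area], so the expected
foreground fraction of a homogeneous band equals the specified layer
density — the property the GLI estimator is tested against. Area identity
at a point follows the nearest foot point on the outer contour; the
per-section ground truth (border arc lengths, labels, seed) is recorded,
and every generator is a pure function of its parameters and seed.

**Profile level.** `simulate_profile_stack()` samples depth-normalized
profiles directly from the laminar density curves with additive Gaussian
noise (default σ = 0.05 per depth sample — the binomial sampling error of
a 16 × 16 field is ~0.03 at mid-range densities, and biological
variability adds to it). The large calibration simulations (300 null
stacks, 200 recovery stacks) run at this level: the statistical contracts
under test live entirely in profile/feature space, and rendering and
re-extracting thousands of full-resolution images would only re-test the
raster chain, which has its own dedicated tests on small sections.

Default study conditions mirror the mapping design they emulate: stacks of
5 serial sections, 100 profiles per section, borders jittered by ≤ 2
profile indices between sections, block sizes 12–30, α = 0.001; cohorts of
10 subjects with alternating male/female assignment (5/5) and shrinkage
factors drawn from 1.5–2.5. The built-in laminar patterns
(`dlpfc_area_specs()`) are loosely inspired by the qualitative contrasts
of the four anterior DLPFC areas (e.g. a thin, blurry layer IV for SFS2, a
broad dense layer IV for MFG2) but no quantitative fidelity is claimed —
the published record contains no laminar density numbers. The recovery
benchmark uses a neutral two-area contrast (layer-IV density 0.2 vs 0.6,
all else equal).

What passing these simulations does **not** show: robustness to staining
artifacts, tissue tears, embedding distortion, oblique sectioning or
curvature-dependent sampling density — none of which the generator
models — nor that the specific published borders or stereotaxic
coordinates would be reproduced, which would require the original
registered material. Printed stereotaxic tables are used only to define
output schemas. The only desk-reproducible published numbers are the
per-brain volume-table aggregates, which the package reproduces exactly
(after the table's integer rounding, half away from zero); two printed
cells of that table do not recompute from their own printed per-brain
values (rounding artifacts in the source) and are excluded from
reproduction checks, documented in the test suite.

## Numerical choices and degenerate inputs

* Laplace: convergence = maximum absolute update per sweep ≤ `tol`
  (default 10⁻⁵); non-convergence at `max_iter` warns and refuses to trace.
* Traverse exclusion threshold: a traverse must reach φ ≥ 0.95 or it is
  excluded (flagged, with a warning).
* All-zero profiles are an error (centre of gravity undefined); a zero
  weighted SD sets skewness and kurtosis to 0; an identically zero
  derivative places its centre of gravity at mid-depth with zero spread.
* All-equal ANOVA cells report F = 0, p = 1 rather than 0/0.
* Ties in the MPM are counted and reported, never silent.
* Simulation problem sizes in tests (300 null stacks, 200 recovery stacks,
  2000 ANOVA null simulations, 100-image conservation checks) were chosen
  as the smallest sets that bound the rates of interest with comfortable
  Monte-Carlo margins.

## Limitations

Sections are processed independently (no 3D traverse computation and no
nonlinear registration — cohort volumes live in one shared synthetic
space, with space ids carried so registered data could be dropped in).
The interactive contour-drawing step of the original workflow is out of
scope: contours are inputs. Assumption tests for the ANOVA
(normality, sphericity, homogeneity) are delegated to standard tools
rather than reimplemented.
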