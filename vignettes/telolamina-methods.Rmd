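---
title: "Quantifying telomere-LAP2alpha association and lamina proximity in 3D-SIM volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying telomere-LAP2alpha association and lamina proximity in 3D-SIM volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telolamina)
```

## The measurement problem

In super-resolved (3D-SIM) images of interphase nuclei, three spatial
questions about telomere biology can be asked quantitatively:

1. **How does LAP2alpha distribute around telomeres?** LAP2alpha is a
   nucleoplasmic lamin-A-binding protein that forms discrete foci; in healthy
   fibroblasts these foci sit close to telomeres (marked by the shelterin
   component TRF1), while in progeria (HGPS) models the association is
   displaced to roughly 360--400 nm from the telomere center.
2. **How much of the nucleus does LAP2alpha occupy, and how much of each
   telomere's surface colocalizes with it?** A per-nucleus coverage
   percentage ("LAP2c") anchors a three-way classification of telomeres into
   low / average / high colocalization.
3. **Where do telomeres sit relative to the nuclear lamina?** A telomere is
   conventionally called peripheral when its center lies within 250 nm of
   the lamina surface.

A fourth, independent stage quantifies per-nucleus mean intensities of two
stains in 2-D fields and their Pearson correlation (e.g. a repressive
chromatin mark against progerin expression).

The package implements all four measurements as a reusable pipeline and
pairs them with a synthetic-volume generator that produces calibrated
volumes with exactly known ground truth, so that every stage is testable
without access to microscopy data.

## Conventions

Volumes are 4-D arrays indexed `(channel, z, y, x)` with per-axis voxel
sizes in nm; the default calibration `(125, 40, 40)` nm uses the common
3D-SIM z-step of 125 nm and a typical reconstructed lateral pitch of 40 nm
(the lateral pitch after SIM reconstruction is instrument-dependent and is a
package default, not a measured constant). Voxel indices are 1-based with
the center of voxel `i` at `(i - 0.5) * spacing`; every distance the package
reports is in nm, so the indexing convention never leaks into results.
Anisotropy is handled explicitly everywhere a distance is computed.

## Pipeline stages and their parameters

### Nucleus segmentation and lamina surface

The nucleus is segmented from a lamina (or DAPI) channel: Gaussian
pre-smoothing (sigma 100 nm, isotropic in physical units), a global Otsu
threshold, per-slice hole filling (turning the hollow lamina shell into a
solid mask), and retention of the largest 6-connected 3-D component, with a
warning when smaller components are discarded. The lamina surface is the
morphological inner boundary of that mask: every mask voxel 6-adjacent to a
voxel outside it.

### Telomere spot detection

TRF1 foci are detected by multiscale Laplacian-of-Gaussian filtering over
four logarithmic scales spanning spot radii 100--400 nm (the scale of
SIM-resolved telomere foci), restricted to the nucleus. A candidate maximum
is kept when two robust criteria both hold inside the nucleus:

* smoothed intensity at the peak `> median + k * MAD`, and
* scale-normalized LoG response `> median + k * MAD` of the response.

The response criterion exists because an intensity cut alone cannot reject
single-voxel shot-noise spikes: over a nucleus of order $10^6$ voxels the
expected number of noise maxima crossing a 3-robust-SD cut is far above one,
whereas a one-voxel spike carries almost no blob mass and fails the response
test. For the same extreme-value reason the default multiplier is `k = 6`
rather than a conventional two-or-three sigma; it is exposed as
`threshold_factor`. Overlapping candidates (center distance below the sum of
the two scale radii) keep the stronger response, which both merges
double-detections of one physical spot across scales and absorbs residual
halo artifacts; truly separate spots at biologically plausible separations
are unaffected. Member voxels are assigned by a seeded watershed on the
smoothed channel over above-background voxels, and centroids are
intensity-weighted. Plateau ties in the maxima are broken towards the lowest
linear voxel index, making detection fully deterministic.

### Projected sections and radial profiles

"Surface" statistics are measured on projected 2-D sections, mirroring how
such data are usually quantified: a slab of z-planes whose centers fall
within a 544-nm window (five planes at the default z-step) is mean-projected.
Around each in-section telomere, intensity is sampled by bilinear
interpolation along eight rays at 45-degree intervals, from 0 to 400 nm in
40-nm steps (the lateral pixel pitch; finer steps add no information below
the pixel size). Rays are truncated where they leave the nucleus section and
truncated samples are excluded from the per-distance mean rather than
zero-filled, which avoids manufacturing artificial decay for peripheral
telomeres.

Two subtleties matter here:

* **Full-thickness restriction.** Near the lateral edge of the nucleus a
  pixel column is only partly inside the projection slab, so its mean
  projection is systematically dimmer. If profiling is allowed there, ray
  truncation interacts with this dimming to imprint a rising radial baseline
  strong enough to mask the displaced-association signal. Profiles (and the
  per-nucleus normalization range) are therefore computed over the region
  whose full slab thickness is inside the nucleus; coverage statistics,
  which are ratios of areas, keep the ordinary any-plane section region.
* **Normalization.** Each profile is rescaled by the min/max of the channel
  over the nucleus section, `(raw - min) / (max - min)` clipped to [0, 1].
  This removes between-nucleus staining differences and makes profiles
  affine-invariant, at the cost of expressing intensity relative to the
  brightest structure in the section.

Aggregation averages the ray-averaged profile of each telomere pointwise
(each telomere contributes once, not each ray), reports the SEM across
telomeres, and takes the peak as the grid distance of the maximum mean
normalized intensity.

### Coverage statistics and categories

Per-nucleus coverage (LAP2c) is the percentage of nucleus-section pixels
positive in the binarized LAP2alpha channel; binarization thresholds are
computed from intensities inside the nucleus only (Otsu by default, or a
quantile rule). Per-telomere coverage is the percentage of the telomere's
member voxels, projected into the section, that land on the projected
LAP2alpha mask. Categories follow self-referential per-nucleus thresholds:
coverage below `LAP2c - sigma` is *low*, above `LAP2c + sigma` is *high*,
otherwise *average*, with boundaries inclusive into *average* (the inclusive
rule is a determinism choice; the underlying convention leaves boundary
behavior unspecified). The spread `sigma` defaults to the standard deviation
of per-telomere coverages within the same nucleus — a deliberately
self-referential choice matching the per-nucleus normalization philosophy of
the profile stage — and can be supplied explicitly instead.

### Lamina distances

Telomere-to-lamina distance is the exact minimum anisotropy-aware Euclidean
distance from the spot centroid (a continuous nm position) to the set of
lamina surface voxel centers. The implementation searches the surface set
exactly rather than sampling a precomputed grid distance transform: a
transform is only exact at voxel centers, and sampling it at off-grid
centroids would introduce up-to-half-voxel errors that the package's own
brute-force-equivalence tests (tolerance 1e-6 nm) would reject. Distances
are measured from the centroid, not the spot surface, matching the
convention of rendering telomeres as center-positioned spheres; the 250-nm
proximity criterion is a parameter.

### Intensity correlation stage

2-D fields are segmented on a marker channel (Otsu, hole fill, connected
components); components below a minimum area or touching the image border
are discarded, and per-component mean intensities of the two measurement
channels are background-corrected by the median of non-nucleus pixels
(configurable off — published descriptions of such analyses rarely state
their background handling, so the default is explicit here). Pearson's r is
reported with the two-sided t-transform p-value and a Fisher-z 95% CI.

### Group comparisons

Condition contrasts use a Welch t-test by default (a pooled-variance option
exists) — the unequal-variance form is the safer default even where
classical Student's t is the common description — and a chi-square test of
homogeneity on category histograms, with categories absent from both groups
dropped and a guard against expected counts below one.

## The synthetic generator

`generate_nucleus_volume()` emulates exactly the statistical structure the
analysis assumes, no more:

* an ellipsoidal nucleus (default semi-axes `(1500, 3000, 3000)` nm, a
  modest flattened fibroblast-like nucleus) with a 120-nm lamina shell;
* `n_telomeres` (default 85, a typical per-nucleus count) placed uniformly
  in the nucleus volume by rejection sampling, optionally with a fraction
  constrained within 250 nm of the surface and a minimum pairwise
  separation; placement failing 1000 attempts raises an error naming the
  constraint;
* ground-truth lamina distances computed analytically (closed form for
  spheres; safeguarded root finding on the Lagrange-parameter equation for
  general ellipsoids, accurate to well below 1e-6 nm);
* LAP2alpha foci of radius 80 nm (~160 nm diameter, the scale of a
  SIM-resolved nucleoplasmic focus): one per associated telomere (default
  association fraction 0.6), displaced by `lap2_offset_nm` in-plane along
  one of the eight 45-degree profiling azimuths chosen at random, plus
  uniform background foci added until the binarized projected coverage
  reaches `lap2_target_coverage` (default 0.157);
* TRF1 foci as 150-nm-radius spheres; all structures blurred by an
  anisotropic Gaussian PSF (sigma `(130, 50, 50)` nm, about 300 nm axial /
  120 nm lateral FWHM) and degraded by Poisson shot noise (1 photon per
  intensity unit, so the default amplitude 100 gives peak SNR 10) followed
  by additive Gaussian read noise.

Three generator choices deserve justification. The LAP2 displacement is
applied *in-plane* because the profile protocol measures displacement in a
projected section; an isotropic 3-D direction would shrink the measured
displacement by the projection factor and make the offset parameter
uninterpretable as the quantity the profiles recover. The azimuth is drawn
from the eight protocol directions rather than continuously: with a
continuous azimuth the nearest ray sees the focus at `offset * cos(delta)`
(`delta` up to 22.5 degrees) and adjacent rays contribute at still smaller
radii, biasing the aggregated peak low by roughly 60 nm — a measurement
artifact of the discrete protocol, not data variance. And the focus radius
must be meaningfully smaller than the displacement being measured; a
structure several hundred nm across cannot resolve a 380-nm displacement in
a radial profile regardless of the analysis.

What the generator does **not** emulate: SIM reconstruction artifacts,
chromatic aberration, intensity heterogeneity within structures, nuclear
invaginations, clustered (non-uniform) telomere placement, or any cell-cycle
structure. Passing recovery tests on this generator therefore demonstrates
that the measurement chain is correct and unbiased under the model's
assumptions — it does not validate the pipeline against the full complexity
of real microscopy data.

The 2-D field generator places non-overlapping elliptical nuclei on a
jittered grid (guaranteeing separation deterministically) and draws
per-nucleus stain means from a bivariate normal with the requested
correlation (mean 100, SD 15; the normal tail below zero is negligible at
these settings).

## Determinism and numerical choices

Everything stochastic flows from a single integer seed (the generator
restores the caller's RNG state). Identical parameters and seed give
bit-identical volumes and ground truth. Degenerate inputs fail loudly:
constant channels cannot be segmented, thresholded or normalized; empty
surfaces and empty projection windows are errors; a spot with no voxels in
the section is skipped with a warning rather than failing the nucleus.
Otsu thresholds use a 256-level histogram over the relevant pixel
population. Watershed flooding and maxima tie-breaks are deterministic by
construction.

## Problem sizes

The validation suite runs entire pipelines, so grid sizes are chosen to
keep a full nucleus analysis at a few seconds: test nuclei use semi-axes
around `(1250, 2200, 2200)` nm (roughly 30 x 120 x 120 voxels) with 30
telomeres, and profile-recovery batches use 20 nuclei per condition
(~200-300 telomere profiles, comparable to the scale at which such profile
averages are typically reported). The acceptance script uses 8 nuclei per
condition for its condition summaries. Statistical recovery checks
(correlation, shell fraction) use 1000-10000 samples where the quantity is
cheap to sample.

## Known limitations

* Coverage quantities are 2-D section areas while lamina distances are 3-D;
  this mixed dimensionality is intentional (it mirrors how such data are
  analyzed) but means "coverage" numbers cannot be compared against 3-D
  colocalization coefficients.
* Min/max normalization is sensitive to single saturated pixels in the
  nucleus section; real data with hot pixels should be despeckled first.
* The spot detector assumes roughly isotropic blob-like foci within the
  scale band; elongated telomere clusters will be split or merged according
  to the scale range.
* The categorization's `sigma` is estimated per nucleus from as many
  telomeres as the nucleus offers; in nuclei with very few telomeres the
  thresholds are noisy.
* EDT-free exact distance search is O(spots x surface voxels); for the
  nucleus sizes this package targets that is milliseconds, but
  whole-embryo-scale volumes would need a different algorithm.

## A minimal end-to-end run

```{r example, eval = FALSE}
p <- synthetic_params(nucleus_radii_nm = c(1250, 2200, 2200),
                      n_telomeres = 30, lap2_offset_nm = 0, seed = 1)
g <- generate_nucleus_volume(p)
res <- analyze_volume(g$volume)

res$nucleus_stats             # LAP2c, sigma, telomere count
head(res$lamina_records)      # per-telomere lamina distances
attr(aggregate_profiles(res$profiles), "peaks")
```
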