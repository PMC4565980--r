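# telolamina

Spatial quantification of telomere–LAP2α association and telomere–lamina
distance in multichannel 3D structured-illumination microscopy (3D-SIM)
volumes, for cell biologists studying nuclear organization (e.g. in
Hutchinson–Gilford progeria syndrome models, where the association between
the nucleoplasmic lamin-binding protein LAP2α and telomeres is disrupted).

The package implements the full measurement chain as composable R
functions, plus a seeded synthetic-volume generator with exact ground truth
so that every stage is validated without access to microscopy data.

## What it measures

Given a calibrated volume with channels for a lamina marker, LAP2α and TRF1
(the telomere-marking shelterin subunit):

1. **Radial LAP2α profiles.** Around each detected telomere, intensity is
   sampled along 8 rays at 45° intervals out to 400 nm on a 544-nm-thick
   projected section, normalized per nucleus to
   `(I − min) / (max − min)`, and aggregated into mean ± SEM curves whose
   peak distance summarizes where LAP2α concentrates relative to telomeres
   (≲200 nm for a tight, wild-type-like association; 360–400 nm for a
   displaced, HGPS-like one).
2. **Surface-coverage classification.** The per-nucleus LAP2α coverage
   LAP2c (% of the nucleus section area positive for LAP2α) anchors a
   three-way per-telomere classification: coverage below `LAP2c − σ` is
   *low*, above `LAP2c + σ` *high*, otherwise *average*.
3. **Lamina distances.** Exact anisotropy-aware Euclidean distance from
   each telomere centroid to the nuclear lamina surface, with the
   conventional 250-nm proximity criterion.
4. **Per-nucleus intensity correlation.** For 2-D two-stain fields
   (e.g. H3K27me3 vs progerin), per-nucleus mean intensities and Pearson's
   r with a Fisher-z 95% CI.

Telomere detection is multiscale Laplacian-of-Gaussian blob detection with
robust (median + k·MAD) intensity *and* response thresholds, watershed
voxel assignment, and deterministic tie-breaking. See the methods vignette
(`vignettes/telolamina-methods.Rmd`) for the model, parameter defaults and
their rationale, and known limitations.

## Worked example

Generate one HGPS-like synthetic nucleus (LAP2α displaced 380 nm from
telomeres, 6.7% target nuclear coverage) and analyze it end-to-end:

```r
library(telolamina)

p <- synthetic_params(nucleus_radii_nm = c(1250, 2200, 2200),
                      n_telomeres = 30, lap2_offset_nm = 380,
                      lap2_target_coverage = 0.067, seed = 1)
g <- generate_nucleus_volume(p)
g$volume
#> <mc_volume> 3 channel(s) [lamin, lap2a, trf1], grid z*y*x = 28x118x118,
#>   voxel (dz,dy,dx) = (125, 40, 40) nm

res <- analyze_volume(g$volume)
res$nucleus_stats
#>  nucleus_id lap2c_percent sigma_percent n_telomeres
#>           1      6.167231      8.834313          30

head(res$lamina_records, 3)
#>  telomere_id nucleus_id distance_nm within_threshold
#>            1          1    508.2430            FALSE
#>            2          1    129.7726             TRUE
#>            3          1    477.2174            FALSE

attr(aggregate_profiles(res$profiles), "peaks")
#> all
#> 400
```

Reading: the analysis recovered all 30 planted telomeres; LAP2α covers
6.2% of this nucleus section (the generator targeted 6.7%); the aggregated
LAP2α profile for this single nucleus peaks at the far end of the 0–400 nm
axis, as expected for a 380-nm displaced association (condition-level peak
estimates use ≥20 nuclei). Each telomere also carries its distance to the
lamina surface and the ≤250 nm proximity flag.

Real volumes enter through `read_volume()` (plain multi-page TIFF with a
JSON sidecar, or OME-TIFF whose `PhysicalSize*` metadata supplies the
calibration), and results leave through `write_records()` /
`build_report()`. A thin command-line wrapper with `simulate`, `analyze`,
`scatter` and `report` subcommands is in `inst/cli/telolamina.R`.

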