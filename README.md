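# cellquant

Quantitative imaging and motility analytics for studies of cortical protein
recruitment in migrating cells.

When signalling proteins (e.g. CEP192, PLK4, active AURKB, DAAM1/2) are
redeployed to the actin cortex of exosome-stimulated cancer cells, the
evidence rests on a chain of bespoke single-cell measurements: mean
fluorescence of a protein of interest inside a ~2 µm cortical ring, in
manually boxed protrusions or in seeded random cortical boxes; total
intensity under a centrosome mask; nuclear-to-cytoplasmic (N/C) ratios;
control-normalised fold changes; mask-based colocalization against a
self-reference ceiling; mean-squared-displacement (MSD) analysis of manual
cell tracks; half-life fits of drug-induced speed decay; and residual
scratch-wound area over time. `cellquant` implements that chain as tested,
reusable R functions, together with a synthetic-data module (cell-image
phantoms, 2D trajectories, wound series) whose known ground truth makes
every stage verifiable end to end.

The core quantities, in the field's standard notation:

* **Cortical enrichment** E = mean POI intensity in the cortical ring /
  mean in the interior cytoplasm; the ring is the cell mask minus its
  erosion by a rasterized disc of radius `round(2 µm / pixel size)`.
* **N/C ratio** ρ = mean nuclear / mean cytoplasmic POI intensity,
  cytoplasm = whole cell − nucleus.
* **MSD** (τ) = ⟨|r(t+τ) − r(t)|²⟩, time-averaged within tracks and
  ensemble-averaged across them; for a 2D random walk MSD = 4Dτ, and an
  OLS fit with R² ≈ 1 marks total random movement, with log–log slope α
  separating diffusive (α ≈ 1) from directed (α → 2) motion.
* **Speed decay** S(t) = S∞ + (S0 − S∞)·2^(−(t − t_drug)/t½), fitted to
  hourly running-average speeds; t½ is the literal half-life.
* **Wound closure**: residual area(t) = 100 · area(t) / area(0) %, sampled
  at 0/6/12/18/24 h.
* **Colocalization**: Pearson r of two channels over the union of their
  Otsu masks, normalised by the self-reference r of one signal imaged
  through two secondary antibodies.

Group reporting matches the conventions of per-cell imaging panels:
median/quartile/min–max summaries, Kruskal–Wallis + Dunn's test against
the control, two-tailed Mann–Whitney U, and two-way ANOVA with Bonferroni
post-tests.

## Worked example

Segment a synthetic cell with 2-fold cortical enrichment and a 0.65 N/C
ratio at 5% imaging noise, and measure both through the full pipeline:

```r
library(cellquant)

ph <- make_cell_image(cell_phantom_spec(
  enrichment_fold = 2, nc_ratio = 0.65,
  noise = list(type = "gaussian", sd_frac = 0.05), seed = 1))

cell <- segment_cell(project(ph$stack, "actin", "average"))
nuc  <- segment_nucleus(project(ph$stack, "dapi", "average"), cell)
ring <- cortical_ring(cell, thickness_um = 2, pixel_size_um = 0.25)
poi  <- project(ph$stack, "poi", "max")

mean_intensity(ring, poi) / mean_intensity(cell & !ring & !nuc, poi)
#> [1] 1.996851   # cortical enrichment; truth = 2
nc_ratio(nuc, cell, poi)
#> [1] 0.6465352  # N/C ratio; truth = 0.65
```

Motility: 40 simulated random-walk tracks (10-min frames, 16 h) analysed
like manual cell tracks:

```r
st  <- simulate_tracks(trajectory_spec("random_walk", n_tracks = 40,
                                       D_um2_h = 50, seed = 7))
fit <- fit_msd_linear(msd(st$tracks))
c(slope_over_4 = fit$slope / 4, r_squared = fit$r_squared)
#> slope_over_4    r_squared
#>   48.6507918    0.9996816   # recovers D = 50; R^2 ~ 1 (random walk)
classify_motion(msd(st$tracks))$class
#> [1] "diffusive"
```

The whole pipeline runs from a config file (see
`inst/extdata/demo_config.yaml`), writing quantification records, speed and
MSD tables, wound series and group summaries as CSV/JSON, reproducibly for
a given seed:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "cellquant"))
```

or from a shell via the thin CLI
`Rscript inst/scripts/cellquant.R run --config inst/extdata/demo_config.yaml`.

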