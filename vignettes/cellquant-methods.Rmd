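---
title: "Methods: single-cell cortical quantification and motility analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell cortical quantification and motility analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellquant)
```

# Scope and measurement model

`cellquant` implements the image-quantification and cell-motility analytics
used to study cortical recruitment of signalling proteins in migrating
cancer cells: where a protein of interest (POI) sits in the cell (cortex vs
interior, nucleus vs cytoplasm, centrosome), how strongly two proteins
colocalize in protrusions, how cells move (random-walk vs directed), how
fast drug treatments shut motility down, and how quickly a scratch wound
closes. Every stage is paired with a synthetic generator that produces the
same kind of data with known ground truth, so the whole chain is testable
without microscopes.

The imaging conventions are fixed throughout: segmentation markers (actin,
DAPI) are quantified on **average** z-projections, the POI on **maximum**
projections; pixel coordinates are 0-based with half-open ROI boxes;
physical distances always go through the pixel size in µm (which must be
user-supplied when files carry no calibration); time is stored in hours
with a default frame interval of 10 min.

# Segmentation and the cortical ring

The cell outline is segmented from the actin average projection by local
adaptive thresholding (`EBImage::thresh`): a pixel is foreground when it
exceeds the local mean by `offset`. Holes are filled and the largest
connected component is kept; an empty result is the error "no cell
detected". The nucleus is segmented identically from DAPI and intersected
with the cell mask, so `nucleus ⊆ cell` holds by construction. Defaults —
window of roughly half the image (clamped to the legal filter size) and
`offset = 0.05` on `[0, 1]` intensities — were chosen on phantoms and are
exposed in the parameters; sparse, well-separated cells are assumed (no
watershed splitting).

The cortical ring "walks inward" from the outline: the ring is the cell
mask minus its morphological erosion by an explicitly rasterized disc brush
of radius `round(thickness_um / pixel_size_um)` pixels (`disc_brush()`,
the set of integer offsets with Euclidean norm ≤ r). The default thickness
is 2 µm, the conventional cortex width. An equivalent formulation
thresholds the Euclidean distance transform at the same radius
(`method = "edt"`); for any mask the two agree exactly, because a pixel
survives erosion by the rasterized disc precisely when its distance to the
nearest background pixel exceeds r.

One rasterization subtlety is worth recording. On a rasterized disk of
radius R, the eroded interior is *not* pixel-identical to the rasterized
disk of radius R − r: grid erosion keeps boundary pixels such as offsets
`(12, 11)` from the centre of an R = 20, r = 4 disk (its farthest in-brush
neighbour has norm √394 < 20 although the pixel itself lies outside the
analytic R − r disk). The discrepancy is confined to the inner ring
boundary (≈1–2% of ring area for cell-sized disks). The package therefore
validates the ring operator against an independent brute-force double-loop
erosion of the same declared brush — which it must match pixel-exactly —
rather than against the analytic disk difference.

## Protrusion boxes and random cortical samples

Protrusions are delineated manually in practice, so they enter as ROI box
files; the measured region is the union of each box intersected with the
ring. For rounded cells without protrusions, `select_random_boxes()`
reproduces the automatic sampling convention: the nucleus is dilated
(default 2 µm, matching the ring thickness, so samples keep the same
clearance from the nucleus that protrusion samples have), the dilated
region is removed from the ring, and two pairwise non-overlapping boxes —
the same size as the protrusion boxes, default 3.88 × 3.88 µm — are drawn
by rejection sampling with box centres on the remaining eligible ring
pixels. The draw consumes an explicit seed and is deterministic given it;
non-overlap is enforced (a convention this implementation fixes where
practice varies), with a default budget of 10,000 attempts before the
shortfall is reported.

# Quantification

* `mean_intensity` — arithmetic mean of POI pixels under a region.
* `centrosome_total_intensity` — sum under the PCNT-derived centrosome
  mask; an empty mask (centrosome-less cells) legitimately yields 0.
* `nc_ratio` — mean nuclear over mean cytoplasmic intensity, cytoplasm
  being the whole cell excluding the nucleus.
* `aspect_ratio` — major/minor axis of the second-moment ellipse. Each
  pixel contributes its unit extent (1/12 variance per axis), which makes a
  perfect a × b rectangle return exactly a/b and keeps one-pixel-wide
  masks finite.
* `normalize_to_control` — intensities become folds relative to the mean
  of control cells *of the same experiment batch*; per batch the control
  folds average to exactly 1. Ratios are stored; percentage display is a
  presentation choice left to reports.

## Colocalization

`coloc_coefficient` builds a foreground mask per channel (Otsu within the
crop by default), combines them, and computes Pearson correlation of the
raw channel values over the combined pixels, so the score reflects signal
intensity and not merely overlap area. The masks are combined by **union**
by default: an intersection would discard signal present in only one
channel, which is exactly the disagreement the coefficient should be
penalising; intersection remains available for sensitivity checks. The
coefficient is invariant to affine intensity rescaling of either channel.
`coloc_normalized` divides by a self-reference coefficient — one protein
detected through two independently labelled secondary antibodies — which
acts as the practical ceiling of measurable colocalization. Constant
channels under the mask make the correlation undefined and are refused.

# Motility analytics

Tracks are centre-of-nucleus positions every 10 min for 16 h (the package
accepts any uniform spacing). `average_speed` is the mean step displacement
over the frame interval; `running_average_speed` tiles hourly windows and
averages the step speeds ending in each window.

The ensemble MSD is time-averaged per track over **all ordered same-track
pairs** at each lag (overlapping windows, chosen for variance reduction; a
non-overlapping variant would discard most pairs), then averaged across
tracks with equal track weight, so n identical copies of a track reproduce
that track's MSD exactly. Lags run to 25% of the shortest track by default,
avoiding the noisy high-lag regime. `fit_msd_linear` regresses MSD on lag
with an intercept (which absorbs static localisation error; a
through-origin option exists); an R² of 1 is the signature of total random
movement, and for a 2D random walk the slope estimates 4D.
`classify_motion` fits the log–log scaling exponent α with a ±0.1 band
around 1 separating diffusive from super-/subdiffusive motion (ballistic
motion approaches α = 2); tracks without positive MSD values are flagged
degenerate rather than fitted.

A practical note on recovering D from one experiment: with 40 tracks of 96
steps the OLS slope of the ensemble MSD carries a sampling error of roughly
5–8% (s.d.), so slope-based D estimates should be averaged over replicate
experiments before being read as bias; the package's own recovery checks
average 25 such replicates.

## Speed-decay kinetics

Drug-washout time courses are fitted by nonlinear least squares
(`minpack.lm`) to
`S(t) = S∞ + (S0 − S∞) · 2^(−(t − t_drug)/t½)`
on post-drug windows. The base-2 form makes `t½` the literal half-life of
the excess speed — the parameter reported for inhibition kinetics (fast,
~1.7 h dual-kinase regimes vs slow, ~5.5 h transcription-block regimes in
the motivating experiments). Because hourly windows average the exponential
over each window, the fitted `S0` absorbs a constant window factor while
the half-life is unaffected — the round-trip on noiseless synthetic decays
recovers `t½` to numerical precision. A flat series leaves the half-life
unidentifiable and is flagged, not fitted; non-convergence is an error
carrying the starting values.

# Wound healing

`wound_area` segments the cell-free band by texture: local variance in a
sliding window (default 3 px), thresholded near zero, dilated by half the
window to undo the variance spill-over at the wound edge, small components
discarded, largest component kept. On noiseless synthetic wounds this
recovers the rendered band to within a pixel column. `residual_series`
expresses areas as a percentage of t = 0 (residual) and its complement
(recovered); sampling at 0/6/12/18/24 h matches the conventional
acquisition design, and a zero initial area is an error ("no wound at
t = 0").

# Group statistics and the pipeline

`summarize_groups` reports median, linear-interpolation quartiles
(`quantile` type 7 — a convention this package fixes explicitly) and
min/max whiskers. `compare_groups` covers the three reporting designs:
Kruskal–Wallis with Dunn's post-hoc test against the control only
(comparisons against the designated control bar; all-pairs optional),
two-tailed Mann–Whitney U, and two-factor ANOVA with Bonferroni-adjusted
within-level post-tests for wound-style condition × timepoint data. Dunn's
test is implemented from its standard definition (pooled-rank z statistics
with tie correction, Bonferroni adjustment) and cross-checked against
hand-computed ranks; adjusted p-values can never undercut unadjusted ones.

`run_pipeline` orchestrates synth → quantify → motility → wound → report
from a validated YAML/JSON configuration. Validation happens before any
computation and collects all schema problems at once. Every random decision
consumes a seed derived deterministically from the configured seed, and a
JSON sidecar records the package version, seed, skipped-cell count and the
full configuration, so identical configurations reproduce identical output
bytes. Per-cell segmentation failures are logged and skipped, not fatal.
The script `inst/scripts/cellquant.R` exposes the stages as thin CLI
subcommands.

# The synthetic generator: what it does and does not emulate

`make_cell_image` renders a disk-shaped cell (optionally with rectangular
actin-rich protrusions), an offset nucleus, Gaussian centrosome foci, and a
POI channel with exact regional structure: cortical band at
`enrichment_fold ×` the interior level, nucleus at `nc_ratio ×` the
cytoplasmic mean (cytoplasm = cell − nucleus, the same convention the
measurement uses). The true ring is generated by the same declared ring
operator, so ground truth and measurement share one geometry definition.
Z-stacks attenuate flanking planes (factor 0.6 per plane) so maximum
projections return the in-focus template exactly. Noise is Gaussian with
s.d. expressed as a fraction of signal amplitude (default 5%, a realistic
mid-range SNR for immunofluorescence), with Poisson shot noise available.

Deliberate idealisations: edges are crisp (no point-spread blur), the
background is flat (no illumination gradients), geometry is circular, and
cells are imaged singly. Passing recovery tests therefore demonstrates
correctness of the measurement chain — segmentation, ring geometry,
regional arithmetic, normalisation — not robustness to optical blur,
clumped cells or stained debris, which real acquisitions add.

`simulate_tracks` covers random-walk (per-axis step variance `2·D·dt`),
ballistic, persistent (wrapped-Gaussian heading increments whose mean
turn cosine is the persistence parameter; used for property tests only)
and decaying-speed models; `make_wound_series` renders a linearly closing
textured band with analytic and rasterized truth areas. All generators are
pure functions of their specification, including its seed.

# Problem sizes and numerical choices

The package's own verification uses 40-track, 96-step motility ensembles
(matching the ≥40 cells per condition convention), 20 phantoms per
enrichment level at 5% noise for E ∈ {1, 1.5, 2, 3} and N/C ratio
recovery (both within ±10%), 10 noisy washout replicates for half-life
recovery (±15% at 10% speed noise; ±1% noiseless), and 5-timepoint wound
series (residuals within 2 percentage points of the analytic closure).
These sizes were chosen to keep the full check suite comfortably
interactive while leaving clear statistical margins.

Other fixed numerical choices: ROI boxes are half-open so areas and
overlaps are exact integer arithmetic; TIFF output quantises `[0, 1]`
intensities to 16 bits (bit-exact round trips on that grid); track time
spacing must be uniform to a relative 1e-6; rejection sampling ties are
broken only by the seeded RNG stream, never by pixel order.

# Known limitations

Protrusion detection is deliberately manual (boxes in, no automatic
detector); multi-cell fields are not split; deconvolution is consumed, not
performed; background subtraction beyond a constant offset, Manders/Costes
colocalization statistics, and leading-edge velocity profiling are out of
scope.
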