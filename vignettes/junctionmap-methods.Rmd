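---
title: "junctionmap: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{junctionmap: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(junctionmap)
```

## What the package quantifies

Epithelial polarity proteins (PAR3, PAR6&beta;, aPKC, CRB3A, PALS1, PATJ)
concentrate near the apical tight junction (TJ) in submicrometric clusters.
Two-color STED-class imaging resolves these clusters at roughly 80 nm, but
turning images into statements like "protein X sits 150 nm apical of the TJ"
or "40% of protein X clusters coincide with protein Y clusters" requires
three quantification steps, each implemented here as an independent module:

1. **Junction-referenced density profiles** (`profile_junction`,
   `pool_density`, `density_map_2d`): intensity profiles sampled
   perpendicular to the junction (planar images) or along the apico-basal
   axis (cryosections), referenced per line to the TJ marker, normalized
   per junction, and pooled into mean &plusmn; SD curves.
2. **Protein&ndash;protein proximity index, PPI** (`extract_band`,
   `correlation_function`, `peak_amplitude`, `proximity_indices`): junction
   bands 400 nm across are straightened, concatenated, and auto-/cross-
   correlated along the junction axis; the index is the ratio of fitted
   correlation peak amplitudes, `P1 = C12/A2` and `P2 = C12/A1`. 0 reads as
   no proximity, 1 as perfect proximity, and intermediate values as the
   fraction of one protein population in close proximity to the other.
3. **Immunogold statistics** (`tj_offsets`, `min_distance_to_polyline`,
   `classify_compartment`, `linkage_fraction`): particle positions from
   electron-tomography projections referenced to the TJ contact point and
   the apical membrane polyline, with an antibody-linkage window (3 nm gold
   radius to ~37&ndash;38 nm primary + secondary antibody reach) deciding
   which particles are compatible with a membrane-anchored epitope.

A fourth module (`detect_clusters`, `region_contingency`) tabulates
detected clusters against annotated microvilli-derived regions, and a
synthetic-scene generator (`scene_params`, `simulate_junction_scene`,
`simulate_pair_with_overlap`, `simulate_gold_particles`) provides ground
truth for every stage.

## The forward model of the generator

Every fluorescent structure is an isotropic 2D Gaussian parameterized by
FWHM (&sigma; = FWHM / (2&radic;(2 ln 2))) and integrated intensity. Because
a Gaussian blurred by a Gaussian PSF is again Gaussian, scenes are rendered
analytically with total variance &sigma;&sup2;_cluster + &sigma;&sup2;_PSF;
this is exact and conserves integrated intensity away from borders (the
conservation test requires better than 1%). The TJ marker is a line source:
a Gaussian cross-section (default FWHM 60 nm) swept along the junction
polyline. Poisson noise, when enabled, is applied last to `gain * image`.

Defaults describe the imaging regime the analysis is meant for:

| parameter | default | why |
|---|---|---|
| `pixel_size` | 20 nm/px | 4 px per PSF FWHM, so sub-pixel logic is exercised |
| `psf_fwhm` | 80 nm | the resolution of the two-color acquisitions |
| `cluster_fwhm` | 80&ndash;200 nm (uniform) | the observed cluster size range |
| `offset_perp_sd` | 60 nm | clusters stay inside the 400-nm analysis band |
| `cluster_amplitude` | 1000 (constant) | no stoichiometry model exists for these clusters; amplitude is a free simulator parameter, and matched amplitudes are the regime in which the PPI reads a fraction |
| `background`, `gain` | 10, 1 | dim, shot-noise-limited background |

Positive perpendicular offsets follow the path tangent rotated +90&deg;
(toward larger y for the default left-to-right path); the same direction is
used as the apical axis in apico-basal scenes, so positive offsets read as
apical of the junction.

What the generator does **not** emulate: non-Gaussian cluster shapes,
fluorophore blinking or bleaching, antibody-displacement of the label
(~25 nm), sample drift, deconvolution artifacts, and 3D structure (scenes
are 2D projections). A green recovery test therefore establishes that the
estimators are unbiased under the stated statistical structure, not that
they are robust to every optical artifact of real acquisitions.

## Density profiles: references, normalization, pooling

* **Planar reference.** Per sampling line, the TJ position is the intensity
  maximum of the reference channel, refined by a three-point parabola; ties
  in the discrete maximum break toward the line midpoint (an unbiased
  choice when a plateau straddles the junction). Constant profiles are a
  hard error: no reference exists.
* **Apico-basal reference.** TJs spread variably (up to about threefold)
  along the apico-basal axis, so the reproducible landmark is the most
  apical crossing of one third of the profile maximum, linearly
  interpolated between samples. Profiles already above threshold at their
  apical end return the end position and are flagged.
* **Normalization.** Per junction, each channel is scaled to unit integral
  by default (`unit_integral`; profiles then read as densities), with
  `unit_max` available. Either removes junction-to-junction intensity
  variation; both are exactly scale-invariant.
* **Pooling.** Lines are averaged within a junction first; mean and sample
  SD (n&minus;1) are then taken across junctions. The junction is the
  statistical unit because junctions, not lines, are independent
  acquisitions. SD across all lines was considered and rejected: adjacent
  lines share clusters and are strongly dependent.
* **Dropped lines.** Sampling lines that leave the image interior are
  dropped and counted, never padded &mdash; padding would bias edge bins
  toward the background value.
* Sampling step defaults to one pixel and the half-length to 1000 nm,
  matching the ~1-&micro;m axis range over which the pooled curves are
  displayed.

## The proximity index

* **Band extraction.** Columns sit at one-pixel arc-length steps along the
  trace, rows at one-pixel steps across, re-centered per column on the TJ
  reference (or on the trace itself for two-protein pairs without a TJ
  channel). 400 nm at 20 nm/px gives 21 rows. Planar junctions failing the
  straightness score (max chord deviation / chord length &gt; 0.05) are
  excluded; curvature would smear the along-junction correlation.
* **Seam handling.** Concatenation records a per-column band id and the
  correlation never pairs pixels across band boundaries. Naive
  concatenation would correlate unrelated junction ends.
* **Correlation normalization.** Pearson on the overlapping support, per
  lag and per band, pooled across bands weighted by pair count. Per-lag
  normalization avoids the bias a single global normalization picks up
  from finite, structured supports, and makes the composite value exactly
  the weighted combination of per-band correlations (tested against
  `stats::cor` per band). Lags run along the junction axis only: the band
  is 400 nm across, too thin for informative across-band lags.
* **Peak amplitude.** Least squares of `baseline + h exp(-lag^2/2sigma^2)`
  over |lag| &le; 5 PSF FWHM, with the linear pair (baseline, h) solved
  exactly on a log-spaced &sigma; grid and golden-section refinement; the
  fitted height `h` is the amplitude. The full pipeline excludes lag 0 from
  all three fits uniformly: Poisson noise is uncorrelated between pixels
  and adds a one-lag self-correlation spike to autocorrelations only, which
  would otherwise deflate `P = C12/A`. Because the treatment is uniform,
  the identity `P(band, identical copy) = 1` is preserved exactly. If the
  fit degenerates, the fallback is the lag-0 value minus the median beyond
  3 PSF FWHM. Negative fitted amplitudes are floored at 0 with a warning
  (they occur in null scenes).
* **No clamping** of P1/P2 by default; Venn fractions clamp at 1 because a
  fraction cannot exceed 1.

### When the index reads the shared fraction

`simulate_pair_with_overlap` copies `round(f n)` of channel A's centers
into channel B and places the rest at least 3 PSF FWHM away from every A
center. Two properties of this stated world matter for interpretation:

1. The exclusion constraint is itself a (negative) spatial correlation:
   where A has a cluster, independent B clusters are forbidden within
   240 nm. At high cluster density this depletion imprints an
   anticorrelation dip on the cross-correlation and biases the index low,
   by roughly `n_clusters x cluster_area / band_area x (1 - f)`. The
   recovery tests therefore use a sparse world (8 clusters per channel on
   ~12-&micro;m junctions) where the depletion term stays well below the
   read-out tolerance of &plusmn;0.10. In real samples no such hard
   exclusion exists; this is purely a property of the generator.
2. `round(f n)/n` must equal `f`, so the recovery tests use a cluster
   count divisible by 4 for f &isin; {0.25, 0.5, 0.75}.

Neither adjustment touches the estimator; both make the simulated truth
equal the nominal `f`.

### Orientation sensitivity

Different proteins at the same apico-basal level can appear to overlap
when projected along a low-resolution axis. The package reproduces this:
rendering the same 150-nm-offset configuration with an 80-nm PSF versus a
550-nm PSF along the offset axis (the axial resolution of an apico-basal
projection) raises the apparent index substantially (tested). The package
computes both orientations and reports both; it does not choose
automatically.

## Immunogold statistics

Coordinates are 2D projections of thin (150&ndash;300 nm) tomograms; 3D
distances are out of scope. Offsets decompose along the apical unit vector
(apical positive) and its perpendicular; the lateral sign convention is
"right of the apical axis positive" (the source data do not fix a
convention; this one is documented and consistent). Point-to-polyline
distance is the exact segment-projection minimum. Compartments are
exhaustive and exclusive: inside a microvillus polygon (even-odd,
boundary-inclusive) &rarr; `microvilli`; else within the vicinity
threshold of the membrane &rarr; `membrane_vicinity`; else `cytoplasm`.
The vicinity threshold defaults to 38 nm, the same bound as the headline
linkage statistic, and is configurable since no separate value is stated
for the compartment summary. Both linkage bounds are computed: the strict
`d < 38 nm` count that the headline fraction uses, and the inclusive
window `3 <= d <= 37 nm` drawn on distance histograms.

The half-normal displacement model of `simulate_gold_particles` reflects
a membrane-anchored epitope labeled through a flexible antibody linkage;
the far-zone uniform component stands in for cytoplasmic label. The
distribution recovery test checks empirical threshold fractions against
the half-normal CDF within binomial 95% bounds.

## Cluster/region contingency

No detection algorithm is prescribed by the source analyses (counts were
reported, not methods), so detection is deliberately plain: Gaussian
smoothing at PSF &sigma;, strict 8-neighbor maxima with relative prominence
&ge; 0.2 of (max &minus; median background), support assignment to the
nearest maximum, intensity-weighted centroids. Prominence is relative, so
detection is intensity-scale invariant. Region polygons are an **input
annotation** (within microvillus / base / between, labels configurable);
the package does not segment microvilli from an actin channel.

## Numerical and interchange choices

* Coordinates: 0-based pixel centers, x = column, y = row; bilinear
  interpolation reproduces affine intensity fields exactly and rejects
  points outside the interior by name.
* TIFF: this R installation ships no TIFF package, so the package carries
  a minimal uncompressed little-endian grayscale reader/writer (8/16-bit
  unsigned, 32-bit float, multi-page). RGB and compressed files are
  rejected explicitly rather than half-read.
* Determinism: all generators take integer seeds and restore the caller's
  RNG state; pipeline outputs are byte-identical under a fixed config and
  seed (tested via md5).
* CSV: comma-separated, header row, '.' decimal; trace coordinates in px,
  EM coordinates in nm; rows may arrive shuffled (vertex order is the
  `vertex_index` column); duplicate vertices are an error, not a silent
  de-duplication.

## Known limitations

* The PPI fraction reading assumes matched cluster counts and amplitudes
  between channels; strongly unbalanced stoichiometry changes the
  autocorrelation amplitudes and with them the scale of P1 vs P2.
* The exclusion-zone depletion above means the generator's null is
  slightly conservative at high density.
* Apico-basal reference flagging (profiles already above threshold at the
  apical end) marks, but does not repair, truncated TJ profiles.
* The EM per-particle source table of the original study is distributed as
  supplementary material that an offline build cannot fetch; the linkage
  statistic is exercised on hand-counted cases and a synthetic stand-in of
  the same size and composition (169 particles, 123 below 38 nm), which
  validates the counting rule but not the published measurement itself.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
p <- scene_params(offset_perp_mean = 150, offset_perp_sd = 30,
                  poisson_noise = TRUE, seed = 7)
sim <- simulate_junction_scene(p)
prof <- profile_junction(sim$pair, sim$trace, half_length = 600)
pooled <- pool_density(list(prof))
pooled$positions[which.max(pooled$mean)]   # ~150 nm, the generated offset

pairs <- lapply(1:10, function(s)
  simulate_pair_with_overlap(scene_params(image_shape = c(192L, 640L),
                                          n_clusters = 8L, offset_perp_sd = 80,
                                          poisson_noise = TRUE, seed = s), 0.5))
res <- ppi_analysis(lapply(pairs, `[[`, "pair"), lapply(pairs, `[[`, "trace"),
                    center_on = "trace")
res$P1                                     # ~0.5, the generated overlap
```
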