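---
title: "From RNA spots to cell types: the fishcall quantification model"
author: "fishcall authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From RNA spots to cell types: the fishcall quantification model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishcall)
```

## The problem

Single-molecule FISH (smFISH) of thick tissue sections produces, after spot
detection and nucleus segmentation (both upstream of this package), two
inputs per field of view (fov): a table of detected RNA spots with 3D
physical coordinates, gene and channel, and a 3D integer-labeled nucleus
mask. In tissue there is no cytoplasmic counterstain, so cells cannot be
segmented directly; instead, the transcripts of a cell-type marker gene
form a dense cloud in the cytoplasm around the nucleus. `fishcall` turns
these clouds into per-nucleus cell-type calls and cell-size estimates and
compares the per-image quantifications between experimental groups. The
motivating application is the murine lung after thoracic irradiation, where
marker-positive proportions (e.g. Lamp3 for AT2 pneumocytes, Chil3 for
alveolar macrophages) and macrophage volumes change as fibrosis develops,
but nothing in the pipeline is organ-specific.

## The procedure and its assumptions

The pipeline runs per fov, in this order:

1. **Autofluorescence removal.** A detection that appears in more than one
   channel at the same location is an autofluorescent particle, not an RNA.
   A spot is removed iff some spot of a *different* channel in the same fov
   lies within the coincidence tolerance (default 0.35 µm — roughly one xy
   pixel at high-NA widefield sampling; this is a free parameter of the
   analysis, not a published constant); both partners of a coincident pair
   are removed. The operation is symmetric and idempotent.
2. **Per-gene clustering.** The spots of each gene are clustered with
   OPTICS (`min_samples = 4`), and a DBSCAN labeling is extracted from the
   reachability ordering at a per-gene radius `eps`. `eps` must absorb the
   gene's expression level and is configured per gene, never estimated:
   `suggest_eps()` proposes the knee of the reachability profile as a
   starting point, but the pipeline only ever consumes the configured
   value. Clusters with fewer than `min_cluster_size = 4` members are
   demoted to noise. DBSCAN leaves the cluster of a border point reachable
   from several clusters unspecified; we fix it deterministically (nearest
   core point, ties to the lowest cluster id) so that memberships are
   invariant to input permutation. Distances are 3D Euclidean in physical
   micrometres; whether the original analysis clustered in 2D or 3D is not
   stated, and 3D is the natural choice for 0.3 µm z-sampling.
3. **Convex hulls.** Each cluster's convex hull (computed by a quickhull
   implementation with exact facet volumes; no 3D computational-geometry
   package is part of this package's dependency footprint) is the proxy for
   the cell territory, and its volume the cell-volume estimate. Collinear
   or coplanar clusters are flagged degenerate with volume 0 and excluded
   from volume statistics.
4. **Nucleus assignment.** For every nucleus, the overlap fraction is the
   share of its voxel centers (in physical coordinates) lying inside the
   hull. A hull is assigned to every nucleus reaching the per-cell-type
   threshold `K`; hulls with no qualifying nucleus are removed (typically
   clouds whose nucleus lies outside the imaged volume). `K` is set per
   cell type (the published range is 20–55%; the default fills the
   midpoint, 0.375). Two readings of the overlap denominator are possible —
   fraction *of the nucleus* captured, or fraction *of the hull* occupied —
   and the source does not disambiguate. Both are implemented
   (`overlap_denominator`); the nucleus denominator is the default because
   `K` is described as accommodating different cell morphologies, which
   reads as "how much of a nucleus must the cloud capture". Nuclei smaller
   than 8 voxels are excluded from overlap statistics to bound
   discretization error.
5. **Typing, proportions, volumes.** Marker positivity of a nucleus is
   "at least one assigned hull of that marker's gene includes it"; each
   cell type is identified by exactly one marker gene. The per-image
   proportion is positives over all segmented nuclei. A hull containing
   several nuclei contributes its volume divided by the number of assigned
   nuclei (average cell volume per nucleus); several same-gene hulls
   claiming one nucleus have their volumes summed. Nuclei positive for two
   markers are reported as co-expressing.
6. **Group statistics.** The statistical unit is the image, never the
   nucleus. Two-sided Mann–Whitney tests compare per-image values between
   groups: the exact null distribution when both groups have at most 10
   untied observations, otherwise the tie-corrected normal approximation
   with continuity correction. The adjustment across a panel's comparisons
   defaults to Holm (the original figures report "adjusted p values"
   without naming a method; Holm is assumption-free and conservative;
   Benjamini–Hochberg and no adjustment are selectable). Stars follow the
   strict legend thresholds: `*` below 0.05, `**` below 0.01, `***` below
   0.001, `****` below 0.0001, `n/s` otherwise (0.05 exactly is `n/s`).

## Probe design

`design_probes()` enumerates every 26–32 nt window of a target transcript
and applies the composition filter: GC in [40%, 60%]; A fraction strictly
below 28%; no `AAAA` run anywhere (read as a global rule, as written —
unlike the C rules it carries no window qualifier); C fraction in
[22%, 28%] (inclusive, as written); and, within the first 12 positions, no
6-nt window containing `CCCC` and none containing four C total. Duplex
stability is scored by the unified nearest-neighbor free energy at 37 °C
(SantaLucia parameters, initiation and self-complementarity terms
included), normalized per nucleotide and expressed relative to a reference
per-nt value (default −1.55 kcal/mol, a GC-rich duplex); candidates within
`dg_band = 0.10` of the target ratio 0.90 pass. The reference and band are
configuration with these documented defaults, since only the "90%"
criterion itself is published. Selection is greedy by closeness to the
target ratio under the constraint of at least 2 unhybridized nt between
selected footprints, up to 30 probes. Probes are emitted as reverse
complements of their target windows (the hybridizing strand) with a shared
FLAP readout appended; the published FLAP Y readout is the default but is
deliberately configuration — the printed sequence has 28 nt while the text
calls it 27 nt, so it is not asserted as a constant.

## Signature scores

`score_cells()` implements the per-cell signature score: each signature
gene is centered and normalized across all cells ("normalized" is read as
division by the standard deviation; the estimator is configurable, sample
`n − 1` by default), and the cell's score is the mean of its standardized
values over the genes used. Consequences that the tests assert: the grand
mean over cells is 0 whenever no gene is dropped, and the score is
invariant to per-gene positive affine transforms. Genes absent from the
matrix and zero-variance genes are dropped with a warning rather than
producing undefined values. Standardization is global across all supplied
cells; per-panel standardization would change the scores and is left to
the caller by subsetting the matrix.

## What the synthetic tissue emulates — and what it does not

`generate_tissue()` builds fovs with the statistical structure the analysis
assumes: a z-stack of 54 planes at 0.3 µm (16.2 µm total; both the plane
count and spacing follow the motivating acquisition protocol, while the xy
pixel size has no authoritative value and must be supplied), non-overlapping
spherical cells with concentric spherical nuclei rasterized at voxel
centers, per-cell Poisson marker-spot counts uniform in the cytoplasmic
shell, homogeneous-Poisson background detections per gene, and
autofluorescent particles duplicated into two channels with Gaussian jitter.
Cells are spheres because the source gives no cell geometry and a sphere
has an analytic volume for oracle tests. Defaults chosen once as realistic
desk-scale conditions: 100 cells per fov, 60 marker spots per positive cell
(marginal DBSCAN connectivity starts below roughly 40 spots per cell at the
default radii), background 0.001 spots/µm³ (~150 false detections per
stack) and autofluorescent particles at 5×10⁻⁴/µm³ with 0.1 µm jitter.

The generator does **not** simulate raw fluorescence images, PSFs,
detection noise, spot-detection misses near the coverslip, irregular cell
shapes, or segmentation errors. Passing the end-to-end tests therefore
shows that the quantification downstream of perfect detection and
segmentation is correct and recovers planted effects; it says nothing
about detector or segmenter quality on real images.

## Study scenarios used by the tests and the acceptance script

Two scenarios exercise the pipeline end to end, with published values used
as *simulation parameters* whose recovery is tested (the original headline
numbers derive from raw images and are not reproducible at desk scale):

* **AT2 proportion study** — control AT2 proportion 12.6% of nuclei
  (the reported control mean), an unchanged group, and a fibrogenic-dose
  group reduced to 4% (the reported decline at five months is pronounced;
  the exact value is not printed, and 4% gives the qualitative pattern —
  a clearly significant drop — at 5 images per group). 100 nuclei per
  image, 5 images per group, marker `Lamp3` at `eps` 2.8 µm, `K` 0.375.
  Recovery is checked against the 95% binomial interval of truth, and the
  Holm-adjusted Mann–Whitney significance pattern across 50 independent
  study seeds.
* **AM volume study** — alveolar-macrophage cell volume 459 µm³ in the
  control and 925 µm³ (ratio ≈ 2.0) in the irradiated group, injected by
  scaling radii by the cube root. The hull volume of a finite spot sample
  underestimates the true cell volume (the hull of ~60 shell points misses
  the outermost rim), but the *ratio* of group medians is scale-free and
  must recover 2.0 within 10%.

Problem sizes (field 100×100 µm in xy, 5 images per group, 12–50 study
replicates depending on the check) were chosen as the smallest at which the
binomial and rank-test arithmetic above gives stable outcomes.

## Numerical choices and degenerate inputs

* Coordinates are `(z, y, x)` everywhere; spots in physical µm, masks in
  voxel indices with voxel centers at `(i − 0.5) · voxel_size` (0-based
  voxel `i−1`), a convention the source never states.
* Quickhull uses an absolute tolerance of `1e-10` times the point-cloud
  extent for visibility tests; hull volumes come from the divergence
  theorem over outward-oriented facets, which is exact for
  lattice-coordinate solids (the unit-cube and unit-tetrahedron tests
  assert equality, not approximate equality).
* Identical constant samples in the Mann–Whitney test return p = 1 rather
  than a division-by-zero; ties disable the exact path.
* Empty spot tables, empty masks, single-channel fovs, and clusters below
  4 members are all legal inputs with defined (empty or noise) outputs;
  configuration errors (a gene without `eps` or a cell type without `K`)
  abort before any computation.
* Every stage is deterministic; the only randomness in the package is in
  the generators, driven by one master seed from which per-fov seeds are
  derived.

## Known limitations

* The hull-based volume estimator is biased low for finite spot counts;
  only ratios and contrasts between groups of comparable spot counts are
  trustworthy, which is how it is used.
* With the nucleus-denominator overlap, a very large hull overlapping many
  nuclei can be assigned to all of them; the per-nucleus volume split
  assumes such multi-nucleus clouds are same-type neighbors, as in the
  motivating tissue.
* `eps` remains a manual, per-gene choice. A poorly chosen `eps` splits
  cells (too small) or merges neighbors (too large); the reachability
  profile helps but does not replace inspection.
* Group comparisons treat images as exchangeable; biological replicate
  structure is carried through (`replicate` column) but not modeled
  (no mixed effects), matching the original analysis.
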