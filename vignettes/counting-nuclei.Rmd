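---
title: "Counting brightly labelled nuclei in 3D confocal stacks"
author: "nuclei3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting brightly labelled nuclei in 3D confocal stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuclei3d)
```

## The problem and the imaging regime

Nuclear markers such as phospho-Histone-H3 (pH3, mitotic cells) and Repo
(glia in *Drosophila*) produce confocal stacks with a very particular
character: nuclei are sparsely distributed, signal intensity is high,
non-specific background is low, intensity decays with focus depth, and the
dominant noise is Poisson photon noise. pH3 stains condensed chromosomes,
so mitotic objects can be irregular; Repo-positive nuclei are round.
Counting these objects by hand is slow and subjective; `nuclei3d`
automates it with a deterministic pipeline, so that the same stack always
yields the same count and all samples in an experiment are treated by
identical criteria.

## The pipeline

For a stack $q(x, y, z)$ of 8-bit slices the stages are:

1. **Median filtering** (2D, per slice, default $3 \times 3$). The median
   suppresses Poisson impulse noise without displacing object borders.
   Intensity operations are deliberately 2D: each slice is about to be
   thresholded on its own terms, and 3D machinery is saved for the binary
   stage where intensity no longer matters.
2. **Per-slice background modelling.** The histogram $h(q)$ of a slice is
   effectively unimodal -- cell pixels are too few to form a visible mode
   -- so classical bimodal thresholding does not apply. Instead a Gaussian
   $G(q) = A e^{-(q-\mu)^2 / 2\sigma^2}$ is fitted by least squares to the
   bins around the background mode, and cell pixels are treated as
   outliers above it. The slice threshold is
   $t = \max(t_{\min},\ \mu + k\sigma)$, default $k = 3$. Because every
   slice gets its own $t$, the depth-dependent intensity decay and abrupt
   slice-to-slice background changes are absorbed without any explicit
   attenuation correction.
3. **Hole filling** (2D, per slice): background components not 4-connected
   to the slice border are set to foreground, so each nucleus becomes
   solid and the distance transform peaks at its centre.
4. **Seeding.** A 3D Euclidean distance transform assigns each foreground
   voxel its distance to the nearest background voxel; nuclei become
   "mountains" of a 4D orographic system. The h-dome transform
   $D_h = q - \rho_q(q - h)$, built on grayscale reconstruction
   $\rho$ (iterated geodesic dilation, 26-neighbourhood), extracts the
   domes of height at most $h$; strictly positive dome voxels form the
   seed mask, its 18-connected components are the seeds, and components
   below 20 voxels are rejected as spurious secondary peaks (true seeds
   are typically an order of magnitude larger).
5. **Watershed.** The foreground is partitioned among seeds with a seeded
   watershed of the inverted distance map computed as an Image Foresting
   Transform: an optimum-path forest on the 6-connected foreground graph
   with bottleneck path cost $\max_{v \in \text{path}} (d_{\max} - d(v))$.
   This separates nuclei that touch in some slices.
6. **Counting.** Objects are relabelled with 6-connectivity through all
   slices, and objects with volume below $V = 3.172\,\mu m^3$ (volume =
   voxel count $\times\, dx\,dy\,dz$) are rejected. Survivors are the
   cells; their number is the count.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `k_sigma` | 3 | -- | outlier cut above the background mean; larger removes foreground pixels |
| `t_min` | 10 | intensity | threshold floor for dark slices |
| `median_radius` | 1 | pixels | half-width of the median window |
| `h` | 7 | voxels | dome height; the standard minimum centre-to-border distance of a cell |
| `dome_threshold` | 0 | voxels | dome binarisation level (strictly above) |
| `seed_min_voxels` | 20 | voxels | minimum seed size |
| `min_volume_um3` | 3.172 | $\mu m^3$ | minimum object volume |
| `intersection_pct` | disabled | % | optional adjacent-slice overlap merge |
| `seed_connectivity` | 18 | -- | seed component labelling |
| `label_connectivity` | 6 | -- | final object labelling |

`h = 7` is an empirical value for embryonic nuclei at the validated
magnification; it marks every cell while splitting very close pairs.
The defaults for `k_sigma` (a standard 3-sigma outlier cut) and `t_min`
are this package's own choices where only the functional form of the
threshold is fixed by the method's description.

The monotone effects exposed by these parameters are tested: foreground
pixels never increase with `k_sigma`, and the cell count never increases
with `min_volume_um3`. The count is also non-increasing in `k_sigma`
*within the outlier-cut regime* ($k \gtrsim 2$); below that the threshold
sits inside the noise band, foreground floods, and separate nuclei merge
-- so the count there is smaller for the wrong reason, and the monotone
claim does not extend to it.

## Numerical and design choices

- **Threshold form.** The method prescribes a cut "standard deviations
  away from the mean" of the background Gaussian plus a minimum
  threshold; this fixes $t = \max(t_{\min}, \mu + k\sigma)$.
- **Fitting interval.** "The interval corresponding to the mode" is
  operationalised as the contiguous run of bins with at least 10% of the
  peak count; this excludes the faint cell tail, which is the point of
  calling cell pixels outliers. The fit is Levenberg--Marquardt least
  squares (A, mu, sigma), initialised at the mode with sigma from the
  half-width at half-maximum; a slice whose fit degenerates (for example
  a constant slice) is marked all-background with a warning, and a stack
  where *every* slice degenerates is reported unusable -- faint samples
  must be discarded, not silently counted as zero.
- **Hole filling is 2D.** A slice-interior hole of a nucleus is
  3D-connected to the outside background through the neighbouring slices,
  so a 3D fill would never close it; the 2D fill is the variant that does
  what the stage is for.
- **Distance metric.** Exact Euclidean distance in *voxel* units,
  ignoring z-anisotropy by default, keeps `h` a pure voxel-geometry
  parameter; `anisotropic_distance = TRUE` weights z by $dz/dx$ for
  users who want physical distances. Distances are measured to in-image
  background only.
- **h-dome floor.** The marker $q - h$ is floored at the image minimum
  (0 for any distance map that touches background), so an image without
  relief has no domes, and $0 \le D_h \le \min(q, h)$ everywhere.
- **Watershed determinism.** The IFT cost is the standard bottleneck
  (max-arc) cost on the inverted distance map; propagation is
  6-connected; seed voxels are finalized before propagation so a seed can
  never be annexed by a neighbour; ties go to the lower seed label, FIFO
  within equal cost. Determinism is what makes "the same stack always
  gives the same count" a testable property.
- **Relabelling after watershed** tracks components within each watershed
  label, so two regions that share a 6-adjacent boundary stay distinct
  instead of fusing back into one object.
- **The adjacent-slice merge** (`intersection_pct`) is implemented in its
  most literal reading -- xy-footprint overlap between labels in adjacent
  slices, relative to the smaller footprint -- and ships disabled: it is
  exposed as a tunable but is not part of the core algorithm.
- **Voxel size.** The z step of the validated acquisitions is 0.5 um; the
  xy pixel size is not recoverable from the acquisition description
  (60x lens, 512x512, no zoom), so the default (0.2, 0.2, 0.5) um was
  chosen once so that the 3.172 um^3 cutoff corresponds to a plausible
  ~159-voxel minimum, and it is loudly overridable everywhere
  (`voxel_size` in [read_stack()], [pipeline_params()], and the CLI).
  Counts depend on it only through the volume filter.

## The phantom generator

[generate_phantom()] renders the regime the method was designed for:
sparse ellipsoidal (Repo-like) or multi-lobed (pH3-like, unions of 2--4
jittered ellipsoids with several local distance maxima, which exercises
the spurious-seed rejection) nuclei of 1.5--3 um semi-axes; expected
signal 200 over background 20 (8-bit); multiplicative depth attenuation
0.991 per slice (about 30% over a 40-slice stack); occasional abrupt
per-slice background shifts (probability 0.1, up to 8 intensity levels);
an isotropic Gaussian blur of 1 pixel as a point-spread proxy; and
per-voxel Poisson noise on the expected counts. Nuclei centres are
rejection-sampled with at least 1 um between bounding spheres -- the
sparse, non-clustered distribution of the validated markers. Everything
is reproducible from `rng_seed`, and the truth labels are exactly the
rendered nucleus voxels before blur and noise.

What the phantoms do *not* model: realistic confocal point-spread
functions (the blur is isotropic Gaussian), photobleaching kinetics,
tissue autofluorescence structure, touching or overlapping nuclei beyond
what `min_separation` near 0 produces, and anatomy. Passing the phantom
batches therefore demonstrates that the algorithm recovers counts in its
designed regime -- sparse bright nuclei over low background -- not that
it handles densely clustered tissue.

The standard validation batches are 10 irregular-mode stacks (65 nuclei
each) and 7 regular-mode stacks (78 nuclei each) of 40 x 256 x 256
voxels, mirroring the scale of the original validation (10 pH3 stacks,
~68 cells each; 7 Repo stacks, ~80 cells each); the unit-test suite uses
12 x 64 x 64 phantoms with 5 nuclei to keep the feedback loop tight.
Pooled object-level sensitivity on both batches, and false-positive and
false-negative rates below 3%, are asserted by the test suite and
recomputed by `scripts/acceptance.R`.

## Validation metric

[match_objects()] compares a detected label stack against truth in 3D by
greedy one-to-one maximal voxel overlap. The one-to-one constraint
encodes the manual error taxonomy: a cell split into two detections is
one match plus one false positive; two cells merged into one detection
are one match plus one false negative. Sensitivity is matched detections
over true cells; identities `tp + fp = detected` and `tp + fn = true`
hold by construction and are asserted on random grids.

## Known limitations

- Densely clustered nuclei whose distance peaks sit below `h` receive a
  single seed and are counted as one; the method targets sparse markers.
- Counts in physical units inherit any error in the supplied voxel size
  through the volume filter.
- Whole-stack results degrade gracefully per slice (failed slices go
  all-background with a warning), but a stack failing everywhere is an
  error by design, not a zero count.
- Label stacks are written as 16-bit TIFF, capping a single stack at
  65535 objects.
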