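# nuclei3d

Automatic counting of sparsely distributed, brightly labelled nuclei in 3D
confocal image stacks — the regime of nuclear markers such as
phospho-Histone-H3 (mitotic cells) or Repo (glia) in *Drosophila* embryos,
where signal is high, non-specific background is low, and intensity decays
with focus depth. Manual counting of such stacks is slow and subjective;
`nuclei3d` replaces it with a deterministic pipeline that always returns
the same count for the same stack, so samples and genotypes are compared
by identical criteria.

## Method

Each slice is median-filtered (3×3) and binarised independently: a
Gaussian G(q) = A·exp(−(q−μ)²/2σ²) is fitted by least squares to the
background mode of the slice histogram, and pixels above

&nbsp;&nbsp;&nbsp;&nbsp;t = max(t_min, μ + kσ),&nbsp;&nbsp;default k = 3

are foreground (cell pixels are outliers of the unimodal background
histogram). Per-slice thresholds absorb depth attenuation and abrupt
background changes without any intensity correction. After 2D hole
filling, a 3D Euclidean distance transform D turns nuclei into
"mountains"; the h-dome transform

&nbsp;&nbsp;&nbsp;&nbsp;D_h = D − ρ_D(D − h),&nbsp;&nbsp;default h = 7 voxels,

where ρ is grayscale reconstruction by geodesic dilation
(26-neighbourhood), marks one seed per nucleus; 18-connected seed
components below 20 voxels are rejected as spurious. A seeded 3D
watershed, computed as an Image Foresting Transform (optimum-path forest
with bottleneck cost on the inverted distance map, 6-connected),
separates touching nuclei. Finally objects are relabelled with
6-connectivity and those below V = 3.172 µm³ are rejected; the survivors
are the cells.

The package also ships a synthetic phantom generator with voxel-accurate
ground truth (Poisson noise, depth attenuation, background jumps,
regular Repo-like and irregular pH3-like nucleus shapes) and an
object-level validation harness reporting sensitivity, false positives
and false negatives.

## Worked example

```r
library(nuclei3d)

spec <- synthetic_spec(nucleus_mode = "irregular", rng_seed = 1L)
ph   <- generate_phantom(spec)
ph
#> <phantom> phantom_irregular_seed1: 65 nuclei (irregular), 40 x 256 x 256 voxels

run <- run_pipeline(ph$image)      # default pipeline_params()
run$result
#> <count_result> 65 cells
#>   volumes: 25.88 .. 86.42 um^3 (median 48.26)
#>   seeds: 65 kept, 3093 rejected; 40/40 slices thresholded

head(run$result$cells, 3)
#>   label voxels volume_um3 centroid_z centroid_y centroid_x
#> 1     1   3780      75.60   32.85185  141.19392   17.58175
#> 2     2   4174      83.48   10.78126   89.17345   20.80906
#> 3     3   1901      38.02   27.75802  228.84271   21.21568

match_objects(run$labels, ph$truth)
#> cells  detected  TP  FP(%)  FN(%)  sensitivity
#>    65        65  65   0.00   0.00  1.000
```

The phantom contains 65 irregular nuclei; the pipeline thresholds all 40
slices, keeps exactly one seed per nucleus (3093 sub-20-voxel noise
domes are discarded), and recovers all 65 cells with no false positives
or negatives. `run$labels` is a label stack aligned voxel-for-voxel with
the input (`write_label_stack()` saves it as 16-bit TIFF), and
`run$result$cells` lists voxel count, volume and centroid per cell.

## Command line

A thin script wraps the same functions:

```sh
SCRIPT=$(Rscript -e 'cat(system.file("scripts", "nuclei3d.R", package = "nuclei3d"))')
Rscript $SCRIPT count stack.tif --voxel-size 0.2,0.2,0.5 --out results/
Rscript $SCRIPT batch stacks/ --config params.txt --out results/
Rscript $SCRIPT simulate --mode regular --seed 3 --out phantoms/
Rscript $SCRIPT validate detected.tif truth.tif
```

`count` prints `name<TAB>count`, writes the label stack, a per-cell CSV
and a per-slice threshold log; `batch` processes a directory (one CSV row
per stack, failures flagged and skipped). Flags override the config
file, which overrides the defaults; exit status 3 flags an unusable
(faint) sample that must be discarded.

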