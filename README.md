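# mpioquant

Volumetric quantification of targeted iron-oxide MR contrast in 3D
T2\*-weighted renal imaging.

## The problem

Micron-sized particles of iron oxide (MPIO) conjugated to an antibody
against an endothelial adhesion molecule (e.g. VCAM-1) bind to activated
endothelium and appear as intense signal voids on T2\*-weighted
gradient-echo MRI. Because the particles are uniform in size and iron
content, the *volume* of induced hypointensity is a quantitative readout of
target expression — in renal ischemia-reperfusion injury it tracks tissue
VCAM-1 mRNA. Turning that idea into numbers requires an objective
segmentation rule, volumetric bookkeeping in physical units, and the
statistics connecting image-derived volumes to qPCR measurements.

`mpioquant` implements that analysis chain for people developing or
validating targeted-contrast quantification methods:

1. **Calibration** — on the pre-contrast scan, compute the mean `μ` and
   sample SD `σ` of the manually masked kidney and place thresholds at
   `μ ± kσ` with `k = 4` by default:
   `low = μ − 4σ`, `high = μ + 4σ`.
2. **Segmentation** — on the voxel-aligned post-contrast scan, label voxels
   `< low` as bound contrast, `> high` as flowing blood (bright-blood
   arteriogram), the rest neutral; ties are neutral.
3. **Quantification** — contrast volume `V = n_low · (FOVx/nx)(FOVy/ny)(FOVz/nz)`
   in µm³ (the reference 25.6×25.6×22 mm / 256×256×96 protocol gives
   2.29×10⁶ µm³ per voxel).
4. **Reconstruction** — a two-channel overlay (contrast → green, blood →
   red) with 3D connected-component labelling.
5. **Kinetics** — organ SNR = mean(organ) / SD(background-noise region)
   over serial time points, with plateau detection of the contrast-volume
   series.
6. **Expression** — comparative-Ct qPCR quantification,
   `fold = 2^(−ΔΔCt)` normalized to a housekeeping gene.
7. **Statistics** — group mean ± SEM, two-tailed Student's *t*-tests, fold
   ratios, and OLS regression of expression on contrast volume (R² =
   squared Pearson correlation).

Because no public imaging data accompany this design, the package ships a
seeded synthetic phantom generator (kidney + vessel tree + liver + noise
background, painted lesion clusters with exact ground truth, saturating
binding kinetics and exponential liver clearance) so every stage is
testable end to end at desk scale.

## Worked example

```r
library(mpioquant)

geom <- acquisition_geometry(fov_mm = c(25.6, 25.6, 22),
                             matrix_size = c(64, 64, 24))
spec <- phantom_spec(geometry = geom, lesion_voxel_count = 1000,
                     n_clusters = 5, seed = 42)
pre  <- generate_precontrast(spec)
post <- generate_postcontrast(pre, spec)

roi   <- kidney_roi(pre$masks)              # parenchyma + vessels
stats <- compute_reference_stats(pre$volume, roi)
thr   <- derive_thresholds(stats, k = 4)
seg   <- classify_voxels(post$volume, roi, thr)
```

```
reference_stats: mean 101.4, sd 18.57 over 8744 voxels
threshold_pair: low 27.08 / high 175.6 (mean 101.4 +/- 4 sd)
segmentation_result: 1000 low (1.467e+11 um^3), 86 high (1.261e+10 um^3) of 8744 voxels in 'kidney_roi'
```

The calibration SD (18.6) exceeds the kidney texture SD (10) because the
bright vessel tree is kept inside the calibration histogram, as it is when
the kidney border is masked manually; the 4-SD band still cleanly separates
lesions (intensity 10) from parenchyma (100) and blood (250). Recovery here
is voxel-exact:

```r
contrast_volume(seg)                  # 1.467e+11 um^3
post$truth$true_lesion_volume_um3     # 1.467e+11 um^3
label_components(seg, connectivity = 26)
```

```
  component_id voxel_count  volume_um3 centroid_x_mm centroid_y_mm centroid_z_mm
1            1         200 29333333333         4.944        15.858      8.195000
2            2         200 29333333333        12.160        11.110      8.589167
...
```

Five components of 200 voxels each — the generated cluster structure —
whose volumes sum exactly to the total contrast volume.

The full experiment (five groups mirroring an injured / sham / IgG-control
/ antibody-blocked / no-surgery design with 5/5/3/2/2 replicates) runs in a
few seconds:

```r
res <- run_experiment(default_run_config())
res$groups
```

```
       group n mean_volume_um3 sem_volume_um3
1        iri 5    175912000000       35925850
2       sham 5     51010666667       29333333
3        igg 3      2640000000              0
4    blocked 2     18333333333              0
5 no_surgery 2      2493333333              0
volume-expression regression: R^2 = 0.969
```

`res$fold_ratios` reports each group mean over the no-surgery baseline
(here 70.6-fold for the injured group, matching its ground-truth lesion
burden of 1200 vs 17 voxels); `res$comparisons` holds the pairwise
*t*-tests and `res$regression` the volume–expression fit. With an output
directory, `run_experiment(cfg, out_dir = "results/")` writes all tables as
CSV plus a hash manifest, byte-reproducibly for a fixed config.

A thin command-line wrapper is installed at
`system.file("cli", "mpioquant.R", package = "mpioquant")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","mpioquant.R",package="mpioquant"))')" \
    --seed 7 --out results/
```

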