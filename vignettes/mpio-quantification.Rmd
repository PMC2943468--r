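---
title: "Quantifying targeted iron-oxide contrast: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying targeted iron-oxide contrast: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpioquant)
```

## The measurement model

Antibody-conjugated micron-sized iron-oxide particles (MPIO) bound to
activated endothelium create local magnetic susceptibility gradients that
destroy signal on T2\*-weighted gradient-echo images. On a bright-blood
acquisition the same image also shows flowing blood as hyperintensity. The
quantification model treats the pre-contrast kidney signal histogram as an
empirical reference distribution with mean $\mu$ and sample standard
deviation $\sigma$, and declares a post-contrast voxel

* **low** (bound contrast) if its intensity is strictly below $\mu - k\sigma$,
* **high** (flowing blood) if strictly above $\mu + k\sigma$,
* **neutral** otherwise,

with $k = 4$ by default. Classified low voxels are summed into a physical
contrast volume using the acquisition geometry: a field of view of
$25.6 \times 25.6 \times 22$ mm at a $256 \times 256 \times 96$ matrix
gives $100 \times 100 \times 229.17\ \mu m$ voxels, i.e.
$2.29 \times 10^6\ \mu m^3$ each. Everything downstream — group summaries,
fold ratios, the regression of relative mRNA expression on contrast
volume — consumes these volumes.

The model's assumptions, stated explicitly:

1. The pre-contrast kidney histogram has a usable mean and SD (it need not
   be exactly Gaussian; the $\pm 4\sigma$ rule only requires that the
   reference spread be meaningful). The synthetic generator uses Gaussian
   texture for the parenchyma accordingly.
2. Pre- and post-contrast volumes are voxel-aligned (animals imaged in a
   fixed cradle). No registration is attempted; a geometry-equality check
   guards the assumption.
3. Intensities are in arbitrary units. Every decision in the pipeline is
   invariant under joint positive affine rescaling $y = ax + b$ of pre and
   post volumes, because thresholds are derived from the same data they are
   applied to. This invariance is enforced by test.
4. Flowing blood is unaltered by bound contrast, so the high class can be
   read as an arteriogram from the same image.

## Threshold calibration choices

**Pooled 3D statistics.** $\mu$ and $\sigma$ are pooled over the whole
masked kidney, not per slice: the reference is "the pre-contrast kidney" as
one region. A `per_slice = TRUE` option reports slice-wise moments for
inspection, but calibration always uses the pooled values.

**Sample SD.** The $n-1$ denominator is used. At calibration sizes
($n \approx 10^4$–$10^6$ voxels) the distinction from the population SD is
numerically immaterial, but the convention is fixed and tested.

**Ties.** A voxel exactly at a threshold is neutral — the classes are
strictly *either side of* the band. With continuous noise ties have measure
zero; in noiseless synthetic data the convention matters and is pinned by
test.

**Vessels in the calibration histogram.** The manually traced kidney border
contains the intrarenal vessel tree, so the bright-blood peak sits inside
the calibration histogram. `kidney_roi()` therefore includes vessel voxels
by default (`include_vessel = FALSE` excludes them). The cost is a modest
inflation of $\sigma$: with the default phantom (vessel at 250 against
parenchyma at $100 \pm 10$, vessels $\approx 1\%$ of the ROI on a
$64^2 \times 24$ grid) the calibration SD is $\approx 18.6$ rather than
$11.2$, and the low threshold lands near 27 — still far above the lesion
intensity of 10. On much coarser grids the thin vessel tree occupies a
*larger fraction* of the kidney (tube voxels scale linearly with grid size,
kidney volume cubically), and below roughly $48^2 \times 16$ the inflation
can push the low threshold under the lesion intensity. Working at such
scales calls for `include_vessel = FALSE`; the package's reduced reference
grid for simulation work is $64 \times 64 \times 24$.

**False-positive budget.** Under a Gaussian reference, $k = 4$ admits a
one-sided tail of $\Phi(-4) \approx 3.17 \times 10^{-5}$ — about 0.3
voxels per $10^4$-voxel kidney — which is what makes fully automated
segmentation trustworthy. The acceptance suite verifies this tail on a
$\geq 10^7$-voxel pure-noise field within Monte-Carlo error.

## What the phantom generator emulates

`phantom_spec()` + `generate_precontrast()` / `generate_postcontrast()`
build a deterministic organ layout from the grid alone (kidney ellipsoid,
thin six-segment vessel tree inside it, liver ellipsoid, an air box used as
the background-noise region; all masks pairwise disjoint), draw Gaussian
tissue texture, and apply one of two acquisition-noise models:

* `gaussian` — additive $N(0, \sigma_{noise})$;
* `rician` — $\sqrt{(s + \epsilon_1)^2 + \epsilon_2^2}$ with independent
  $N(0, \sigma_{noise})$ channels, the magnitude-reconstruction model of MR
  data. Gaussian is the default: the threshold rule is stated on the
  empirical histogram and works under either model, and at the SNR regimes
  simulated here ($s/\sigma \gg 3$ inside tissue) the Rician bias is small.

Post-contrast lesions are painted, not physically modelled: exactly
`lesion_voxel_count` parenchyma voxels are set to `lesion_intensity`,
grown from uniformly sampled cluster seeds by nearest-neighbour accretion
into `n_clusters` contiguous blobs that are forbidden from touching each
other (26-neighbourhood), so the generated cluster count is exact by
construction. The accretion order is recorded; serial series take prefixes
of it, so lesion sets are nested over time and clusters grow in place.

Default intensities (arbitrary units): parenchyma $100 \pm 10$, vessels
250, lesions 10, liver 150, air 0, acquisition noise 5. They encode the
contrast regimes the method needs — a deep signal void well below the
$4\sigma$ band and a bright-blood peak well above it — while keeping the
vessel peak a small mode of the histogram, as in a real pre-contrast scan.

Kinetics: the bound fraction follows the piecewise-linear saturation
$\min(1, t/t_{plateau})$ with $t_{plateau} = 60$ min (binding evident well
before the plateau and stable after it); only the qualitative shape is
specified by the biology, so the simplest saturating form is used. The
liver mean decays as $floor + (base - floor)\,e^{-t/\tau}$ with
$\tau = 15$ min, putting most clearance inside the first 30 minutes and a
steady state by 60 min. `uptake_t50_min` is recorded for provenance; under
the linear model it is implied ($t_{plateau}/2$).

Paired expression values are linear in true lesion volume with additive
Gaussian noise, floored at zero — the structure the volume–mRNA regression
assumes.

**What the phantom does not emulate** — and hence what passing tests do
*not* show about animal data: susceptibility physics (lesion contrast does
not depend on particle load, echo time or field strength), partial-volume
mixtures at lesion borders, cardiac/respiratory motion and gating
artifacts, coil-sensitivity bias fields, anatomical variability of the
vascular tree, and any registration error between scans. Results on the
phantom validate the *bookkeeping and statistics* of the pipeline, not the
biology or the physics.

## Kinetic summaries

`organ_snr()` is mean(organ)/SD(background region). "Noise" is the SD of
the background-region intensities; the background mask must be disjoint
from the organ. A zero noise SD raises an error rather than returning an
infinite SNR. SNR is invariant to pure rescaling; an additive offset $b$
shifts it by $b/\mathrm{SD}_{noise}$ (tested, since it is a practical
pitfall when scanner offsets differ between time points).

`plateau_time()` reports the earliest time after which every subsequent
relative change of the contrast-volume series is below `rel_tol` (default
5%). Changes are normalized by the **series maximum**: a plateau tolerance
relative to the running value would divide by zero at the pre-injection
baseline. A still-rising series returns the final time point flagged
`reached = FALSE`.

## Expression and statistics conventions

The comparative-Ct implementation aggregates replicates by mean Ct before
differencing, fixes amplification efficiency at 2 (no efficiency
correction), and uses the mean $\Delta Ct$ of a designated calibrator
*group* as the reference, matching group-relative reporting. Two exact
identities are enforced by test: encoding any fold $F$ as Ct values and
decoding returns $F$ to machine precision, and adding a constant number of
cycles to every Ct leaves all results unchanged.

`compare_groups()` is the classical pooled-variance two-tailed Student's
*t*-test (`var.equal = TRUE`), with a paired option because
clamped-vs-contralateral comparisons are within-animal; the pipeline
reports both where group sizes allow, and records NA when both groups are
exactly constant (which genuinely happens with voxel-exact recovery). No
multiple-testing correction is applied across the pairwise tests — a
deliberate caveat, not an oversight: the analysis reports a small set of
pre-planned contrasts.

`fit_linear()` is ordinary least squares with $R^2$ equal to the squared
Pearson correlation; a flat response is reported as $R^2 = 0$, $p = 1$
rather than NaN.

## Reconstruction conventions

Connected components of the contrast channel default to 26-connectivity —
clusters of discrete particles appear as diagonally touching voxel runs,
and 6-connectivity would split them. Components are labelled via a
voxel-adjacency graph; volumes conserve the total low-signal volume
exactly, and centroids use the voxel-centre convention (voxel $i$ spans
$[(i-1)\Delta, i\Delta]$, centre $(i - \tfrac12)\Delta$).

## Pipeline and reproducibility

`run_experiment()` drives phantom generation → calibration →
classification → component labelling → paired expression → group
statistics → regression for a multi-group design, with every replicate's
seed derived deterministically from the config's `base_seed`. All random
draws go through `withr::with_seed`, so generators are bit-reproducible
and never disturb the caller's RNG state. Output tables are written with
stable formatting and hashed into a manifest; two runs from the same
config are byte-identical.

The default configuration mirrors a five-group design (injured n = 5,
sham n = 5, IgG control n = 3, antibody-blocked n = 2, no surgery n = 2)
with ground-truth lesion burdens of 1200/348/125/18/17 voxels — the
printed group-mean contrast volumes of the motivating experiment scaled by
a common factor onto the reduced grid — and an expression model (slope
$3.0/(1200 \cdot v_{vox})$ per µm³, intercept 0.05, noise SD 0.3) that
places the injured group near relative expression 3 over a baseline of
0.05.

## Problem sizes

Simulation-backed checks run on reduced grids chosen as the package's
working scale for desk simulation: $64 \times 64 \times 24$ for
segmentation-recovery and pipeline runs (single replicates take well under
a second), $128 \times 128 \times 72$ for moment checks needing
$\geq 10^5$ kidney voxels, a $256 \times 256 \times 160$ pure-noise field
($\geq 10^7$ voxels) for the false-positive tail, 20 seeded replicates for
noisy volume recovery, and 500 replicates of $n = 12$ pairs for regression
recovery. The full-protocol geometry ($256 \times 256 \times 96$) is the
default for interactive use.

## Known limitations

* Lesions are intensity-painted; no Bloch/susceptibility simulation, so
  sensitivity questions (how much iron gives how much signal loss) are out
  of scope.
* No registration: misaligned pre/post volumes are rejected, not fixed.
* The coarse-grid vessel-fraction effect described above: below about
  $48^2 \times 16$, calibrate with `include_vessel = FALSE`.
* Rician noise biases background statistics upward (Rayleigh mean
  $\sigma\sqrt{\pi/2}$); SNR values under the Rician model are therefore
  not directly comparable to Gaussian-model runs at the same
  $\sigma_{noise}$.
* The expression simulator draws independent noise per kidney; it does not
  model shared animal effects, so the regression-recovery results say
  nothing about mixed-effects structure.
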