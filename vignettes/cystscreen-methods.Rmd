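---
title: "Methods: quantifying 3D cyst-growth screens with cystscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying 3D cyst-growth screens with cystscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cystscreen)
library(dplyr)
```

## The assay and what the package computes

Renal epithelial cells grown in a 3D hydrogel form hollow cysts: a
spherical epithelial monolayer with an actin-rich wall surrounding a
fluid-filled lumen. Raising intracellular cAMP (forskolin stimulation)
drives cyst swelling; compounds that block the swelling are candidate
modulators of cystogenesis. A screen images each well of a 384-well
plate as a z-stack of wide-field fluorescence planes in two channels —
actin (rhodamine-phalloidin) and nuclei (Hoechst) — and asks, per well:
how large are the cysts, what do they look like, and how many cells are
present?

`cystscreen` implements the full analysis path:

1. **Segmentation** (`segment_plane()`, `detect_cysts()`): per-plane
   monochrome masks of the actin channel, linked across planes so that
   vertically overlapping cysts are counted as separate objects.
2. **Per-object and per-well features** (`compute_object_features()`,
   `aggregate_well_features()`): pixel area, perimeter, circularity,
   wall thickness and wall ratios, intensity statistics, object and
   nuclei counts.
3. **Normalization and QC** (`normalize_plate_median()`,
   `normalize_to_control()`, `normalize_percent_inhibition()`,
   `zprime()`): plate-median z-scores, control-anchored z-scores,
   percent inhibition, and the replicate-adjusted Z'-factor.
4. **Hit calling** (`call_hits()`): the cyst-size rule on replicate
   means.
5. **Phenotype profiling** (`rank_features_by_zprime()`,
   `fit_phenotype_space()`, `project_phenotypes()`,
   `classify_phenotypes()`): a Z'-gated, standardized 3-component PCA
   with restored / unchanged / novel classification.
6. **Synergy** (`analyze_synergy()`): Bliss independence on
   two-compound dose grids.
7. **Orchestration** (`run_pipeline()`): one config, deterministic
   stage-wise re-runs, CSV outputs and a manifest.

Because raw screening images of this kind are rarely shared, the
package ships a seed-controlled generator (`simulate_screen()`) that
renders synthetic two-channel z-stacks with exhaustive ground truth;
every quantitative claim the test suite makes is a recovery statement
against that truth.

## The replicate-adjusted Z'-factor

Assay quality between the stimulated (max) and unstimulated (min)
control groups is summarized as

$$Z' = \frac{\left(\mathrm{AVG}_{max} - 3\,\mathrm{SD}_{max}/\sqrt{n}\right)
            - \left(\mathrm{AVG}_{min} + 3\,\mathrm{SD}_{min}/\sqrt{n}\right)}
           {\mathrm{AVG}_{max} - \mathrm{AVG}_{min}},$$

where $n$ is the number of technical replicates. The $\sqrt{n}$ term
shrinks each 3-SD band to the standard error of a replicate mean: it is
the separation relevant to a screen whose readout is the mean of $n$
replicate wells. At $n = 1$ the classical Z'-factor is recovered. The
statistic is monotone decreasing in either SD, increasing in $n$,
invariant under affine rescaling of both groups, and never exceeds 1.

The same statistic gates features for profiling
(`rank_features_by_zprime()`). There $n$ is the screen's
technical-replicate count (quadruplicates by default), not the control
group size: control groups are usually much larger than the test-well
replication, and the gate should judge separability at the replication
the screen actually uses.

**Direction of the gate.** The feature screen retains features whose
between-control Z' exceeds the cutoff (default $-1.0$). A literal
"keep features with Z' below $-1.0$" would retain exactly the features
that carry *no* control separation and discard every discriminating
one, so the cutoff is read as a lower bound. The default of $-1.0$ is
deliberately permissive: features with modest separation still carry
phenotypic signal once combined by PCA.

## Normalization layers

All descriptors are first z-scored to the plate median (robust scale,
MAD $\times$ 1.4826, by default; sample SD is selectable) to remove
plate effects, then z-scored to the unstimulated-control median so that
0 means "looks untreated". For dose-response visualization the size
feature is instead rescaled linearly so the stimulated-control median
is 0% and the unstimulated-control median 100% inhibition. Percent
inhibition is *not* clamped: values above 100% (wells smaller than
untreated) are a meaningful overshoot phenotype. Only the Bliss
analysis clamps effects into $[0, 1]$, because the independence model
treats them as probabilities.

A compound is a **hit** when the replicate-mean control z-score of the
size feature is $\le 0$ — equal to or smaller than the unstimulated
median — at *any* tested dose. Means are used rather than single wells
because the screen design reports quadruplicate means; a minimum of two
evaluable replicates is required per dose.

## Phenotype space and classification

Selected features are standardized (centre + unit variance — they mix
pixel areas, ratios and counts on incommensurate scales) and
decomposed by PCA into three components named PC0, PC1, PC2. Loadings
are sign-fixed (largest-magnitude loading positive) so refits are
bit-reproducible. The space is fitted on all wells of the run by
default; fitting on controls only is possible by subsetting the input.

Classification works on replicate-mean scores per compound-dose:

* **restored** — within a Mahalanobis radius of the
  unstimulated-control centroid (nearer centroid wins when inside
  both);
* **unchanged** — within radius of the stimulated centroid;
* **novel** — outside both, *or* the replicate-mean nuclei count falls
  below a configured fraction (default 0.5) of the
  unstimulated-control median. The nuclei override captures cytotoxic
  wells whose size features alone can masquerade as rescue.

The covariance behind the Mahalanobis distance is pooled over both
control groups and lightly regularized. The radius (default 8) and the
nuclei fraction are configuration parameters, not estimates: the
boundary between "same as control" and "new phenotype" is a judgment
the bench scientist makes visually on cluster plots, and we set the
defaults by requiring that, on simulated screens with known truth,
fully rescuing non-toxic actives land inside the unstimulated band
while cytotoxic wells (which sit 15+ units away or fail the nuclei
rule) never do. At desk scale the radius must absorb centroid and
covariance estimation error from small control groups (4 wells per
group in the demo screen); screens with full 16-well control groups
can tighten it.

## Bliss synergy

Single-agent effects $E_A$, $E_B$ and observed combination effects
$E_{AB}$ are scaled sizes in $[0,1]$ (0 = stimulated median, 1 =
unstimulated median). The Bliss prediction is
$E = E_A + E_B - E_A E_B$ and the combination index is
$CI = E / E_{AB}$: observed stronger than predicted ($CI < 1$) is
synergy, weaker ($CI > 1$) antagonism. CI is computed per dose pair on
replicate means, with an additivity band of $\pm 0.05$ around 1
(the model itself only defines the two strict inequalities; the band
keeps pure sampling noise from being labelled an interaction). A zero
observed effect leaves CI undefined rather than infinite.

## The synthetic screen generator

`simulate_screen()` emulates the statistical structure the analysis
assumes, not the optics of a microscope:

* **Geometry.** Cysts are spheres sampled by equally spaced focal
  planes; each intersection renders as a bright actin ring of
  configurable thickness around a dim lumen. The z-spacing (50 µm)
  versus the lateral pixel size (3.25 µm) makes the sampling strongly
  anisotropic, so a typical cyst intersects 1–3 planes — which is why
  vertical linking, not 3-D reconstruction, is the right segmentation
  model. Spheres are placed with 3-D exclusion (best-effort rejection
  sampling): real cysts are solid structures in a gel and do not
  interpenetrate.
* **Stimulation and dose response.** Forskolin swells cysts by a
  configurable factor (default 1.6 on the radius). A compound's Hill
  effect acts linearly on median cyst *area* — the measured size — so
  percent inhibition is linear in the true effect. `max_inhibition`
  may exceed 1: the strongest actives in a real screen suppress
  forskolin-independent growth too and end up *below* the unstimulated
  median, and the demo active (1.1) reproduces that overshoot. At
  effect exactly 1 the well reproduces the unstimulated radius draw on
  the same random substream.
* **Toxicity.** Toxic compounds fragment the actin wall (integrity
  < 1 removes ring arcs), deplete nuclei and shrink radii in
  proportion to their effect — the small-disintegrated-cysts,
  low-cell-count phenotype.
* **Nuclei.** Per-cyst counts are Poisson with mean proportional to
  the radius (cells tile the wall); spots are Gaussian, placed on the
  sphere surface, and rendered into the nearest plane.
* **Noise.** Additive Gaussian noise on a constant background, 16-bit
  quantization, optional lateral illumination gradient. No PSF,
  photobleaching, debris or gel autofluorescence.
* **Reproducibility.** One master seed; each well draws from a
  substream derived by a fixed counter scheme (`well_seed()`), so any
  well can be regenerated alone and whole screens are bit-identical
  across runs.

What passing tests on this generator *do* show: the segmentation
recovers object counts and areas from ring-shaped objects across the
realistic size range, the vertical-overlap resolution works, the
normalization/QC/hit/profiling/synergy mathematics behaves as
specified, and the pipeline discriminates the three phenotype
archetypes at realistic noise. What they *cannot* show: robustness to
optical artefacts, debris, segmentation of deformed or collapsed
cysts, or any property of a specific real cell line.

## Numerical choices

* **Thresholding** is Otsu on the range-normalized histogram of the
  smoothed plane, with an absolute intensity floor (default 2000)
  guarding near-empty planes where Otsu would split background noise.
  Otsu on the normalized histogram makes noise-free segmentation
  invariant to intensity rescaling.
* **Smoothing** uses a small Gaussian (σ = 0.7 px). Larger kernels
  dilate small objects: at radius 5 px even half a pixel of boundary
  bias is a 20% area error.
* **Hole filling** closes the dim lumen into the mask so "area" means
  whole-cyst area, not ring area.
* **Vertical linking** joins objects in adjacent planes whose masks
  overlap by ≥ 0.5 of the smaller mask, greedily one-to-one per plane
  pair (largest overlap first, ties toward the lower plane). Each
  linked group reports the plane of maximal area — the equatorial,
  best-focus plane.
* **Perimeter** is the Cauchy–Crofton-corrected boundary edge count
  (exposed 4-neighbour edges × π/4), which is asymptotically exact for
  smooth convex digital shapes; circularity $4\pi A / P^2$ is clamped
  to 1 because digital squares would otherwise exceed it.
* **Wall band**: mask plus a 1-px dilation margin, thresholded at the
  midpoint between the median interior (lumen) intensity and the
  brightest band pixel; mean thickness is wall area over perimeter. A
  uniform-intensity object therefore has thickness exactly 0.
* **Nuclei counting** runs on the maximum-intensity projection
  (nuclear shape is not resolvable at low magnification): smoothing,
  Otsu + floor, then an intensity watershed (tolerance 0.008 of the
  normalized range) to split touching spots. Residual undercounting
  (~5–10% at realistic densities) comes from genuine xy-overlap after
  projection and is irreducible without 3-D nuclei segmentation.
* **Degenerate inputs**: constant planes segment to nothing; zero-object
  wells are retained with missing aggregates (a zero count is itself a
  cytotoxicity readout); features constant on a plate are flagged
  rather than divided by zero; equal control anchors are an error.

## Problem sizes

The demo configuration (`demo_screen_config()`) is the package's
desk-scale study: a 4 × 8 plate (three compounds at 0.1 and 1 µM in
quadruplicate, plus 4 + 4 control wells), 5 focal planes of
192 × 192 px, 6–10 cysts per well. The full-scale defaults
(`screen_config()`) describe the production geometry (16 × 24 plate,
25 planes, 1024 × 1024 px, 100–150 cysts per well) and are used by the
image-free statistical layer (`simulate_combination()`), where the
per-well cost is negligible. Segmentation benchmarks use a dedicated
dense fixture (64 cysts, radii 5–40 px, 8 vertically overlapping
pairs, noise-free).

## A worked demo

```{r demo, eval = FALSE}
out <- tempfile("cyst-demo")
manifest <- run_pipeline(demo_screen_config(seed = 1), demo_compounds(), out)
manifest
readr::read_csv(file.path(out, "hits.csv"))
readr::read_csv(file.path(out, "labels.csv"))
```

## Known limitations

* Laterally touching cysts in the *same* plane merge into one object;
  only vertical overlap is resolved. With realistic packing this is
  rare and the per-well medians are robust to it.
* The wall-thickness estimate degrades for cysts whose equivalent
  radius approaches the wall thickness (interior statistics become the
  wall itself); such objects are flagged.
* The phenotype classifier assumes the two control clusters are
  approximately elliptical in PC space; heavily multimodal controls
  would need a finer reference model.
* The generator's defaults are conventions where the acquisition
  hardware is undocumented (camera bit depth, pixel size, frame size);
  they are configuration, not facts about any instrument.
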