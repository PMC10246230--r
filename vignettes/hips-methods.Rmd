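---
title: "HiPS: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HiPS: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hips)
```

## The problem

Nottingham grading summarizes breast-cancer histology with three visual
criteria scored by a pathologist. It ignores most of the tumor
microenvironment (TME): cancer-associated fibroblasts (CAFs),
tumor-infiltrating lymphocytes (TILs), the collagenous stromal matrix, and
the spatial arrangement of all of these around the invasive epithelium. This
package computes a transparent, hypothesis-driven catalogue of TME features
from panoptic-segmentation outputs of H&E whole-slide images — a semantic
region mask (epithelium / stroma / TILs-dense / necrosis) plus a table of
classified nuclei — and combines the most prognostic features with the
ER/PR/HER2 panel into a single interpretable survival score, the Histomic
Prognostic Signature (HiPS).

The package deliberately starts *after* segmentation: any panoptic
segmentation model that can emit a label mask and a nuclei table with
classification probability vectors can feed it. A synthetic slide and cohort
generator with known ground truth stands in for real whole-slide images, so
every stage is testable without clinical data.

## The feature catalogue

`hips_manifest()` defines 109 patient-level features in 5 themes (epithelial,
stromal, TILs, necrosis, interactions) and 26 subthemes. The full published
catalogue is not reproduced verbatim anywhere in text form, so the shipped
manifest is a reconstruction constrained to exactly that structure: it
contains every feature name the literature quotes (`quoted = TRUE` rows, e.g.
`LocalTILsDensity32uM`, `CAFDensityAtEpithNestMargin`,
`PeriCAFMatrixHeteroIn512uMROI`, `NoOfLowGradeNucleiPerEpithNest`,
`ChromatinClumpingOfEpithNuclei`, `CFOD`) plus systematic family expansions:
mean/sd pairs, the three interaction radii (16/32/64 µm), and per-superclass
variants.

The feature families, and the conventions that matter:

* **Global densities** — counts per mm² of analyzed tissue (non-background
  mask area), plus the global necrosis fraction.
* **Region morphology** — the 1 µm/px mask is downsampled to 2 µm/px
  (nearest neighbor), each class is dilated with a 5×5 pixel (10×10 µm)
  square element, holes smaller than 48² µm² are filled, 8-connected
  components are extracted, and components of at most 128² µm² are dropped.
  The hole count records retained (large) holes only; whether small holes
  should count before filling is not specified anywhere, and counting
  retained holes matches the glandular-lumen interpretation of the feature.
  Perimeter uses a chain-step estimator (axial steps weight 1, diagonal 1.3)
  calibrated so digital disks give circularity 4πA/P² within a few percent
  of 1 and squares within a few percent of π/4; raw boundary-pixel counting
  would bias circularity above 1.
* **Nuclear morphology** — nuclei are rasterized from their ellipse or
  polygon geometry at the image resolution (0.5 µm/px by convention). Shape
  comes from the instance masks; intensity and Haralick texture (contrast,
  correlation, energy, homogeneity, entropy; 32 gray levels, distance 1)
  from the hematoxylin-proxy channel; chromatin clumping is the fraction of
  Canny edge pixels inside the nucleus. The Canny thresholds are the Otsu
  split of the gradient magnitudes restricted to nucleus pixels, with an
  absolute gradient floor (0.03) so featureless noise yields no edges.
* **Deep ratios** — TILs activation p(plasma)/p(TILs), epithelial atypia
  p(cancer)/p(epithelial), CAF epithelialization p(fib)/(p(fib)+p(cancer));
  invariant to rescaling the probability vector, NA on a zero denominator.
* **Cytoplasmic rims** — intensity/texture within 4 µm of the nuclear
  boundary. Rim pixels reachable from two nuclei are excluded from both
  (computed by min/max grayscale dilation of the label image), which makes
  per-nucleus rim statistics unambiguous at the cost of discarding contested
  pixels.
* **Local density and clustering** — mean neighbor counts within 16/32/64 µm
  (inclusive distances; the center cell is excluded from same-class counts,
  the standard Ripley convention, since the count should measure *other*
  cells). The clustering ratio divides the mean local count by its
  complete-spatial-randomness expectation λπr², with λ computed on the
  analyzed tissue area, not the bounding box. No edge correction is applied:
  tissue extent is large relative to r ≤ 64 µm, giving a small negative bias
  near borders (the CSR calibration test shows mean ratios around 0.94-0.95
  on a 1 mm² window at r = 64 µm, inside the accepted [0.9, 1.1] band).
* **Stromal matrix and collagen** — peri-CAF matrix heterogeneity is the
  variance, across a 512 µm ROI, of per-CAF mean rim intensities restricted
  to stromal matrix (stroma minus all nuclei). Collagen fibers are Canny
  edge components (≥ 10 px, nuclei and a 2 µm halo around them masked out —
  without the halo, nuclear-boundary gradients dominate the edge threshold)
  with length, orientation and axis ratio from second moments; fibers with
  axis ratio < 0.2 count as straight. CFOD is the normalized Shannon entropy
  of a length-weighted orientation co-occurrence matrix over 36 bins of 5°;
  all fiber pairs in the ROI co-occur (no pairing kernel is specified in the
  method this follows, and the all-pairs reading is the simplest). Fiber
  waviness is 1 − chord/arc per fiber, with the arc measured along a binned
  centerline of the component (robust to Canny producing a two-sided edge
  ribbon per fiber); it is a reconstruction, since no formula for waviness
  is published. Fibroblast orientation entropy pools the orientations of
  CAFs within 64 µm of each CAF (the largest clustering radius; the radius
  is otherwise unspecified) and normalizes the binned entropy to [0, 1];
  near-circular nuclei have no orientation and are excluded.

## Saliency and aggregation

Nuclear and stromal-matrix features are computed per ROI and weighted by the
ROI's *saliency*, which prioritizes the cancer–stroma interface:

$$ \mathrm{saliency} = \frac{\text{area of stroma within } 32\,\mu m
\text{ of epithelium} \times \text{area of epithelium}}
{\text{area of non-necrotic tissue}} $$

computed on tile-area fractions (a common scaling leaves rankings and
normalized weights unchanged). The stromal band is obtained from a
slide-wide distance transform of the epithelium mask, so adjacency across
tile borders counts. Whether the denominator should include background is
unspecified; here it is the non-necrotic *tissue* fraction. Tiles are
512×512 µm (nuclear features, top 128 by saliency) or 256×256 µm
(stromal-matrix features, top 256), retained when tissue composition is at
least 50% (inclusive); partial edge tiles are kept and evaluated on their
true area so tumor at slide borders is not discarded.

Aggregation recipes: region features → unweighted per-WSI mean and
population sd; whole-WSI statistics (densities, clustering, interactions) →
computed once per slide to avoid artificial ROI-boundary artifacts;
per-nucleus features → per-ROI mean and sd, then saliency-weighted mean over
the top-k ROIs. For `_Std` features the quantity aggregated is the per-ROI
*cell-to-cell* sd (then saliency-weighted), matching the "cell-to-cell
variation" reading of variance features; the weighted sd convention is the
frequency-weight (population) one. Multiple slides per patient are averaged
feature-wise. After aggregation, features are z-scored against the
discovery-cohort statistics and missing values (absent tissue, e.g. no
TILs-dense regions) are filled by 10-nearest-neighbor imputation against the
reference cohort, with distances computed on mutually observed z-scored
features; z-scoring follows patient-level averaging, matching the order in
which the processing steps are described. Fibers are detected once per slide
and assigned to 256 µm ROIs by centroid — one edge pass instead of one per
tile, and fibers crossing tile borders are not split.

## The prognostic model

`hips()` fits the signature end to end:

1. univariable Cox regression (Breslow ties) of every z-scored feature;
2. admission of the most prognostic feature (smallest Wald p; ties to larger
   |log HR|, then name) per subtheme — 26 features;
3. the four IHC inputs ER, PR, HER2 and the derived TNBC indicator join, for
   30 inputs in total (TNBC is collinear with its components by
   construction; the elastic-net penalty handles this, and the model keeps
   all four as specified);
4. an elastic-net Cox fit over penalty strengths 10⁻⁴…10 (10 log-spaced)
   crossed with L1 ratios {0.1, 0.5, 0.9}, chosen by 5-fold cross-validated
   concordance (the grid and objective are this package's choices; only
   "cross-validation over alpha and L1 ratio" is prescribed);
5. the training log partial hazard is mapped affinely onto [0, 10] using the
   training minimum and maximum; out-of-sample scores are clamped;
6. a 3-component Gaussian mixture (unequal variances, EM via mclust) is fit
   to the training scores; the two risk-group cut-offs are the closed-form
   crossing points of the weighted component densities between consecutive
   component means (midpoint fallback if no crossing lies between them;
   tertile fallback if the mixture degenerates). Group intervals are
   [0, t1), [t1, t2), [t2, 10]; the released thresholds are 3.6 and 6.0.

Thematic subscores decompose the score over six groups (five themes + IHC):
subscore_g = a·Σ_{j∈g} β_j x_j + b/6, so the six subscores sum to the score
exactly; allocating the intercept evenly is this package's choice, as only
additivity itself is prescribed. The control model applies the same
machinery to Nottingham grade + IHC; because grade is discrete, its score
histogram is discrete and the range is split into three equal intervals
instead of mixture crossings. `fit_epithelial_variant()` restricts the
pipeline to epithelial subthemes + IHC. Univariable screening uses z-scored
features (screening follows the z-scoring step in the pipeline order).

## The synthetic generator

`simulate_slide()` emulates exactly the structures the features measure:
epithelial nests (wavy ellipses with controllable size and circularity,
optionally with necrotic cores), TILs-dense aggregates, nuclei placed by
homogeneous Poisson or Thomas (Neyman–Scott) processes — the two regimes the
clustering statistics must distinguish — with near-one-hot probability
vectors, and a grayscale H&E-like rendering: dark nuclei with chromatin
speckle, mid-gray stroma, dark oriented collagen segments whose orientations
(shared with fibroblast nuclei) are von-Mises distributed with concentration
`collagen_kappa`. Default rates (CAF ≈ 200/mm², TILs ≈ 200/mm², epithelial
nuclei 2500/mm² within nests, 250 fibers/mm²) are in the range a pathologist
would call plausible for invasive carcinoma at the rendered contrast, and
fiber density is kept sparse enough that individual fibers remain resolvable
at 0.5 µm/px — the regime in which edge-based fiber isolation is meaningful.

`simulate_cohort()` draws standardized latent parameters per patient
(CAF abundance, TILs abundance, collagen disorder, atypia, necrosis), maps
them to generator settings, and draws survival from an exponential hazard
h₀·exp(Σβz) with independent exponential censoring calibrated to the target
censoring fraction; IHC prevalences are ER 80%, PR conditional on ER, HER2
15%, and grade derives from atypia tertiles.

What the generator does *not* emulate: color (images are grayscale-rendered;
Macenko normalization is exercised separately on two-stain RGB mixtures with
known stain vectors), scanner and staining batch effects, segmentation
errors (probability vectors are near-one-hot by construction), lobular or
diffuse growth patterns, fat/vessels/DCIS, and realistic chromatin texture.
Passing tests therefore demonstrate that the measurement pipeline recovers
known generative structure, not that the features are prognostic in real
tissue.

## Problem sizes and reproducibility

The end-to-end demonstration (`run_endtoend_demo()`) simulates 200 patients
with one 384×384 µm slide each (a single 512 µm ROI and a 2×2 grid of
256 µm ROIs per slide — enough to exercise every aggregation path while
keeping the demonstration a few minutes long on one core), drives the hazard
through stromal latents (β = 0.6 CAF, 0.45 collagen disorder, −0.35 TILs),
and compares the fitted signature against the grade+IHC control; with a
stroma-driven hazard the signature's concordance exceeds the control's. All
randomness derives from one master seed fanned out through fixed per-module
substreams, so identical seeds give bit-identical cohorts, features and
fits.

```{r demo, eval = FALSE}
demo <- run_endtoend_demo(seed = 1, n_patients = 200)
print(demo)
plot(demo$fit)        # score histogram + mixture components + thresholds
plot(demo$eval_hips)  # Kaplan-Meier curves by risk group
```

## Known limitations

* The clustering statistics carry the stated negative edge bias near tissue
  borders; on very small fields (≪ 1 mm²) the CSR calibration degrades.
* The manifest is a structural reconstruction; feature-by-feature identity
  with the original catalogue beyond the quoted names cannot be claimed.
* CFOD's pairing rule and bin count, the fibroblast-orientation radius, the
  waviness formula, and the per-subscore intercept share are explicit
  substitutes where the source methods leave details unstated; each is
  flagged above.
* Univariable screening and selection reuse the full training cohort, as in
  the original design; the cross-validated concordance guards the elastic
  net's hyperparameters, not the screening step.
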