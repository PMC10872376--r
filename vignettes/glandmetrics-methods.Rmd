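---
title: "Gland histomorphometry and recurrence modeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gland histomorphometry and recurrence modeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glandmetrics)
```

# The problem

After radical prostatectomy, serum PSA should fall to zero; a later rise to
0.2 ng/mL or above defines biochemical recurrence (BCR). The question this
package addresses is whether quantitative features of gland morphology,
measured automatically on digitized whole-mount H&E slides, carry information
about which patients will recur. The pipeline has five stages: tile
extraction driven by pathologist annotations, stain-deconvolution
segmentation of each tile into lumen / epithelium / stroma / background,
per-gland histomorphometry, tumor-volume estimation from a prostate voxel
mask, and a statistical battery relating patient-level feature vectors to the
BCR label and to time-to-recurrence.

Because real whole-mount cohorts cannot ship with a package, every stage is
driven by a synthetic generator with analytically known ground truth. The
generator is first-class, tested code: its closed forms are what the test
suite and the acceptance script check recovery against.

# Synthetic slides

A synthetic gland is an elliptical lumen (semi-axes $a, b$, orientation
$\theta$) surrounded by a uniform epithelial ring of thickness $t$ — the
Minkowski dilation of the lumen by a disc of radius $t$. This choice makes
every measured quantity analytic:

* lumen area $\pi a b$, lumen perimeter by the elliptic integral
  $4\int_0^{\pi/2}\sqrt{a^2\sin^2\phi + b^2\cos^2\phi}\,d\phi$;
* epithelial ring area $P t + \pi t^2$ where $P$ is the lumen perimeter;
* wall thickness exactly $t$ everywhere on the ring (an enlarged ellipse
  with semi-axes $a+t, b+t$ would *not* have this property: its minimum
  gap to the inner ellipse is below $t$ away from the axes, which is why the
  ring is defined as a dilation).

Rasterization measures the dilation between pixel centers, which undercounts
the continuous ring by up to ~3.5 % for thin rings; the renderer therefore
includes pixels within $t + 0.25$ px of the lumen set, centering the
discretization error. Rasterized areas then agree with the closed forms to
within 2 % for semi-axes of 20 px and above, which is the regime the tests
operate in.

Glands sit on an eosin-dominant stroma rectangle inside a white border.
Colors are rendered through the Beer–Lambert model
$I = I_0\,10^{-c^\top M}$ using the conventional Ruifrok–Johnston H&E
optical-density vectors (with a unit cross-product residual channel), i.e.
exactly the model the segmenter inverts, so at zero noise the segmentation
is exact by construction. Epithelium is rendered hematoxylin-dominant
(concentrations 0.9 H, 0.15 E) and stroma eosin-dominant (0.1 H, 0.7 E);
additive Gaussian pixel noise is available (`noiseSd`, default 0 so closed
forms hold). When `stromaFraction` is supplied, the tissue rectangle is
sized so that stroma / (stroma + epithelium) matches the target
(rectangle area = lumen + epithelium / (1 − f)); otherwise the rectangle is
the image minus `backgroundMargin`.

What the generator deliberately does **not** emulate: nuclear texture,
cribriform multi-lumen architecture, scanner color profiles, stain
variability, tissue folds and tears. Passing tests therefore demonstrate
that the measurement code is correct on geometry it was not fitted to — not
that segmentation is robust to real-world staining variation.

# Tiling and tile selection

Slides are divided into square tiles named by their 0-based x/y grid indices
(`x{ix}_y{iy}`); scanners in the source setting used 3000 px or 5100 px
tiles, and the size is a parameter here. Partial tiles at the right/bottom
edges are kept — features are normalized by actual tile area, so a half tile
of the same tissue texture reports the same fractions. Tiling is an exact
partition: stitching the tiles back reproduces the slide byte-identically,
which the tests assert.

White space is flagged by mean optical density below a threshold (default
0.05), playing the role of an averaged white-image background correction
that is scanner-specific and not portable. Annotations are split into
regions of interest, one per 8-connected lesion. Per lesion, 5 tiles are
drawn uniformly without replacement among eligible tiles — 15 for
non-atrophic benign tissue, to balance the benign and cancer pools — and a
lesion offering fewer than 5 eligible tiles is skipped entirely.

Eligibility is "more than 50 % within the mask after white-space removal".
The denominator is ambiguous in prose, so both readings are implemented
behind `coverageDenominator`; the default is **tissue pixels** of the tile,
on the rationale that a tile that is mostly blank glass but whose tissue is
entirely in-lesion should qualify. Benign lesions with at least 5 but fewer
than 15 eligible tiles return all eligible tiles: the 5-tile skip rule is
the only stated minimum. Annotations drawn at lower scanner resolution are
brought into the analysis frame by nearest-neighbor rescaling (label set
preserved exactly); no intensity-based registration is attempted, accepting
the minor alignment error that re-scanning introduces.

# Segmentation

RGB is converted to optical density ($OD = -\log_{10}((I+\epsilon)/I_0)$,
clamped at zero), deconvolved per pixel by solving $od = c\,M$ with
concentrations clipped at zero, and classified: tissue pixels are epithelium
where hematoxylin concentration ≥ eosin, stroma otherwise. Morphological
closing (disc radius 2 px) and a minimum object size (30 px) smooth the
epithelium mask; both are configuration parameters since no canonical values
exist. White space splits into **lumen** — white fully enclosed by tissue,
found by hole-filling — and **background** — white connected to the image
border. The four masks are disjoint and exhaustive on every input; this is a
class validity invariant, not just a convention. An optional block-mean
downsampling by an integer factor (conventionally 2) trades resolution for
speed; areas in physical units agree within 5 % for glands ≥ 50 px across.

# Histomorphometry

Glands are lumen–epithelium pairs: each lumen component is assigned to the
epithelium component whose filled hull contains it; several lumina inside
one epithelium (cribriform-like) form one gland whose lumen area is the sum
and whose wall thickness is the minimum. Lumina with no surrounding
epithelium are excluded and tallied; epithelium without a lumen is kept as a
gland with zero lumen area (cell fraction 1, wall thickness missing).

Per-gland features, all in physical units:

* **area** — pixel count × (µm/px)², reported in mm²;
* **perimeter** — traced Freeman chain of the region contour with Kulpa's
  calibrated step weights (0.948 straight, 1.340 diagonal). Naive pixel-edge
  counting overestimates a disk's circumference by ~27 % and raw chain
  length by ~5.5 %, which would bias roundness low; with the calibrated
  weights a digital disk of radius 50 px measures roundness 1.010.
  Single-pixel regions use a perimeter floor of 4 weighted steps.
* **roundness** — $4\pi A / P^2$; 1 for a circle, $\pi/4$ for an ideal
  square with polygonal perimeter $4s$. Digital roundness may slightly
  exceed 1; no clamp is applied and 1.1 is the accepted ceiling.
* **wall thickness** — minimum distance between the lumen contour and the
  outer contour of the filled gland, in mm. Measured against generated
  rings this recovers the generating thickness to within one pixel (the
  contour-to-contour distance between pixel centers sits ~1 px inside the
  continuous value).
* **cell fraction** — epithelial area / (epithelial + lumen area). The
  source phrasing ("percent of epithelial cells per total gland area,
  defined by the area of the epithelium without lumen") is ambiguous; the
  adopted reading excludes lumen from the numerator and uses
  epithelium + lumen as the denominator, giving a value in [0, 1] with
  lumen-free glands at exactly 1.

Tile summaries take unweighted means over glands plus stromal/epithelial
area fractions normalized by actual tile area; glands clipped by a tile
border are measured as-is. Patient aggregation averages tile rows within a
group — all tiles, cancer only (G3, G4NC, G4CG, G5), noncancer only
(benign, atrophy, HGPIN, seminal vesicle) — or, for whole-slide analysis,
averages within slides first so each slide carries equal weight.

# Tumor volume

Prostate volume is voxel count × voxel volume from a binary NIfTI mask.
Each slide's cancer ratio is the annotated cancer area over total tissue
area. At the patient level, cancer and tissue areas are **pooled** across
slides before dividing (area-weighted), rather than averaging per-slide
ratios — robust to small edge slides and consistent with summing areas
before normalizing; per-slide averaging is available via `pooling = "mean"`.
Tumor volume = pooled ratio × prostate volume, so it can never exceed the
prostate volume.

# Statistics

* **BCR labeling**: recurrent iff any post-surgery PSA ≥ 0.2 ng/mL
  (inclusive); event time is the first crossing, otherwise censoring at last
  follow-up.
* **t tests**: pooled-variance two-tailed by default (Welch optional);
  degenerate zero-variance groups with equal means report p = 1.
* **Logistic models**: maximum likelihood via `glm`; accuracy is
  resubstitution accuracy at probability 0.5 (no cross-validation, matching
  a single-fit design; the threshold is a parameter). Complete separation is
  flagged on the result rather than raised.
* **ROC/AUC**: Mann–Whitney concordance from midranks (ties count 1/2),
  with a DeLong 95 % CI; the implementation is authored here and
  cross-checked in tests against brute-force pair counting and pROC.
* **AUC comparison**: paired randomized permutation test — both models
  score the same subjects, so the null swaps the two models' scores within
  subjects; p uses add-one smoothing over 10,000 permutations by default and
  is calibrated (type-I error ≈ 0.05 in the test suite's 500-replicate
  null).
* **Multiplicity**: Benjamini–Hochberg step-up, flags and monotone adjusted
  p-values.
* **Survival**: Kaplan–Meier product-limit curves with log-rank p;
  Cox proportional hazards with Efron tie handling, Wald CIs, and a
  convergence flag (simplified models are the caller's recourse).
* **Risk strata**: pathomic probability ≥ 0.2 = high risk (threshold chosen
  on the ROC curve in the source setting); CAPRA 0–2 / 3–5 / 6–10; Grade
  Group 1–2 / 3 / 4–5; cribriform absent/present.

# Synthetic cohorts

The cohort generator encodes two known structures. Recurrence labels are
Bernoulli with $P(\text{BCR}) = \operatorname{logit}^{-1}(\beta_0 +
\beta^\top (x - \mu))$ on Gaussian features (centering makes the intercept
the marginal log-odds; defaults $\beta_0 = \operatorname{logit}(0.2)$ — a
roughly 20 % recurrence rate, matching a contemporary prostatectomy cohort —
with coefficients 0.8 on lumen roundness and −0.5 on wall thickness).
Each patient receives a twice-yearly PSA series consistent with the label,
so `labelBcr()` recovers the generating labels exactly. Separately, a
survival arm draws exponential event times at a known hazard ratio
(default 2) between two groups, with independent exponential censoring
truncated at a 7.3-year horizon (default censoring rate 0.2). Clinical
covariates (age ~ N(59, 6.4), log-normal preoperative PSA, Grade Group
frequencies 18/51/15/2/14 %, CAPRA, 34 % cribriform presence) are shaped
like a prostatectomy cohort for pipeline plumbing.

Problem sizes used by the tests and the acceptance script — logistic
recovery at n = 5000 over 100 replicates, Cox recovery at n = 2000 over 50
replicates, permutation calibration over 500 null replicates of 40 subjects
with 200 permutations each — were chosen as the smallest sizes at which the
asymptotic checks (CI coverage, mean HR, type-I error) are stable.

# Numerical choices and degenerate inputs

Zero-gland specs render an all-white slide with an empty truth table;
overlapping or out-of-bounds glands are errors. Empty cohorts yield empty
tables. The optical-density clamp $\epsilon = 10^{-6} I_0$ keeps OD finite
at zero intensity. Deconvolution refuses stain matrices with condition
number ≥ 100. Ties in tile selection are broken by uniform sampling under
the caller's seed; all generators save and restore the caller's RNG state.
Seeds reproduce outputs byte-identically.

# Known limitations

Synthetic glands are convex rings; real prostatic glands are crenellated,
and cribriform lesions have many lumina per gland — the pairing logic
handles the topology but the geometry tests do not probe extreme shapes.
Segmentation thresholds are calibrated to the rendering model; on real
scanner output the stain vectors and the white threshold would need
per-scanner configuration. Accuracies are resubstitution values, not
cross-validated. The permutation comparison assumes both models score the
same subjects (paired design); unpaired comparisons are out of scope.
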