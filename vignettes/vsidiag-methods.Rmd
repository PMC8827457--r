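---
title: "Methods: automatic VSI interpretation with vsidiag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic VSI interpretation with vsidiag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

Volume sweep imaging (VSI) standardizes obstetric ultrasound acquisition:
eight probe sweeps over external landmarks — four vertical passes from the
maternal pelvis to the fundus at increasing lateral offsets, four
horizontal passes from the maternal right to the left flank at increasing
axial levels — each stored as an ordered cine stack of 2D grayscale
frames. An operator needs hours, not years, of training. The interpretive
burden then falls on whoever reads the clips. `vsidiag` automates that
reading: it segments the fetal head and the placenta frame by frame,
converts per-sweep detections into a spatial likelihood map of the
pregnant abdomen, classifies fetal presentation and placental location
from that map, and measures biparietal diameter (BPD) and head
circumference (HC) from the best head mask.

All modules share one normalized coordinate frame: **axial** 0 = pelvis,
1 = fundus; **depth** 0 = anterior (probe side), 1 = posterior;
**lateral** 0 = maternal right, 1 = left.

## The sweep phantom

No patient scans ship with the package, so the `phantom` module renders a
synthetic abdomen through the same sweep geometry and is the substrate for
every test:

* the abdomen is a homogeneous mid-gray block (default 300 × 260 × 150 mm);
* the fetal head is an ellipsoid with a bright rim (skull) and dark
  interior, default semi-axes (42, 55, 44) mm along (axial, lateral,
  depth). The shortest axis deliberately points along the maternal axial
  direction, so the transverse sweep plane through the head centre carries
  the two largest semi-axes — exactly the plane a sonographer would use
  for BPD/HC. Ground truth is analytic: BPD = 2 × second-largest
  semi-axis, HC = Ramanujan perimeter of the maximal cross-section
  ellipse;
* the placenta is a 30 mm slab on the anterior wall (depth ≈ 0.04–0.24),
  the posterior wall, or across the fundus (axial ≈ 0.86–0.96);
* speckle is multiplicative unit-mean gamma noise with variance
  `noise_level` (default 0.1) — the simplest one-parameter texture with
  ultrasound-like statistics. With `noise_level = 0` the rasterization is
  returned bit-exactly, which the tests exploit;
* cephalic phantoms place the head's axial centre in [0.16, 0.40],
  non-cephalic in [0.60, 0.84], so recovery tests have unambiguous labels
  (cephalic ⇔ axial centre < 0.5 is the package-wide convention).

**Sweep imaging model.** A vertical sweep produces transverse sections at
its frame positions, imaging the full lateral extent (a convex probe's
wide sector); its registry *band* is only a map-assignment region. A
horizontal sweep produces sagittal sections imaging just its axial band
(the probe's axial footprint), so a detection along it localizes the
structure laterally while the band pins it axially. This split is what
makes the voting scheme below geometrically consistent, and it keeps the
full biometry plane visible to the vertical sweeps.

The exact anatomy of the eight clinical sweeps is site procedure, not
code: the registry (`default_registry()`) — vertical bands centred at
lateral 0.2/0.4/0.6/0.8, horizontal bands at axial 0.2/0.4/0.6/0.8, each
0.25 wide — is plain JSON-serializable data and can be replaced wholesale.

What the phantom does **not** emulate: acoustic shadowing, attenuation,
probe-pressure deformation, fetal limbs and trunk, twins, amniotic-fluid
variation, and the anisotropic point-spread function of a real transducer.
Passing tests therefore demonstrate the correctness of the *pipeline
logic* (geometry, voting, scoring, measurement) and the learnability of
clearly delineated structures, not clinical segmentation performance.

## Segmentation

The segmenter is the classical U-Net contract: `depth` encoder levels of
two 3×3 convolutions (batch normalization + ReLU after every convolution),
2×2 max-pooling, a two-convolution bottleneck, and a decoder of 2×2
stride-2 up-convolutions with skip concatenation, ending in a
sigmoid-activated 1×1 convolution. Filters double after each downsampling
and halve after each upsampling; weights are He-initialized. At the
default depth 4 the enumeration gives 2(d+1) + 3d + 1 = 23 convolutional
layers, counting up-convolutions. Training uses Adam on binary
cross-entropy with batches of 16 shuffled frames; Dice and Jaccard are
monitored per epoch. 80% of the structure-present frames form the training
positives, 20% the validation set; structure-absent frames all join the
training split. One model is trained per structure; the placenta's uneven
texture converges more slowly, hence the separate default epoch counts
(20 head, 40 placenta).

Because the environment provides no deep-learning runtime, the network is
implemented in the package: 3×3 convolutions as im2col + GEMM and the
fused BN+ReLU forward/backward in compiled code, pooling/up-convolution/
concatenation as vectorized R. The backward pass is verified against
central-difference numeric gradients in the unit tests. With deterministic
BLAS, training is a pure function of (data, config, seed).

Numerical choices: binarization threshold 0.5 (the sigmoid midpoint, the
standard convention); BN ε = 1e-5, running-statistics momentum 0.9;
Adam (0.9, 0.999, 1e-8), learning rate 1e-3; an all-negative dataset is
trainable (the 80/20 split then covers all frames) so that learning the
empty prediction is testable; a non-finite loss aborts with the epoch
index. A training dataset with no frames at all is an error.

A **ground-truth oracle segmenter** satisfies the same `predict_mask()`
contract by returning the phantom's stored mask for each frame. Plugged
into the pipeline it must produce perfect downstream metrics — the tests
assert exactly that — which separates pipeline errors from model errors.

## Detection series and the likelihood map

Per sweep, a frame is a *detection* when its predicted mask reaches
`min_area_px` (default 30 at 128×128 ≈ 0.2% of the frame); runs of
detections shorter than `min_run = 3` are cleared, since a structure that
clips the imaging plane for only a frame or two is an unreliable cue.
Both filters are configurable; the defaults are the package's own choice
of guard against this failure mode.

The map is a zero matrix with rows = the largest vertical sweep's frame
count and columns = the largest horizontal sweep's; shorter sweeps are
rescaled by nearest-index (floor) resampling, the identity when lengths
match. Vertical sweeps add 1 to the rows at detected positions within
their lateral band; horizontal sweeps to the columns within their axial
band. Pre-smoothing values are therefore integers bounded by the number of
sweeps, the map is invariant to sweep order, and adding a detection never
decreases a cell — all asserted as properties, plus exact equality with a
brute-force indicator summation on small random exams. A separable
Gaussian (reflective boundary, σ = 0.03 × max(dimension) by default, σ = 0
allowed) smooths the counts; reflective padding with a normalized kernel
preserves total mass, which matters because the classifiers use mass
centroids. Increments are binary presence per frame, not mask area: the
voting scheme treats "structure seen here" as one unit of evidence
regardless of cross-section size, which keeps sweeps with different
frame sizes commensurable.

## Diagnosis

The axial × lateral map cannot distinguish the anterior from the posterior
wall — that is the third (depth) axis. The within-frame depth centroid of
the detections (0 = near field), area-weighted across frames, supplies it.
Decision rules, all thresholds in `classifier_params()`:

* presentation: axial centroid < 0.5 → cephalic, else non-cephalic;
  centroid rather than argmax because the smoothed map can be multimodal;
* placenta: (1) empty map → indeterminate; (2) axial centroid ≥ 0.75 →
  fundal — decided *before* depth because a fundal placenta straddles both
  walls; (3) depth ≤ 0.45 → anterior; (4) depth ≥ 0.55 → posterior;
  (5) otherwise fundal (straddling);
* axial centroid ≤ 0.10 raises the low-placenta (previa-suspect) referral
  flag — a screening cue, not a validated diagnosis.

Centroids are ratios, so classification is invariant to uniform scaling of
the map, and flipping the axial axis exchanges cephalic and non-cephalic;
both are property-tested. The rule set and every threshold are declared
package design decisions and parameterized for substitution, since no
single quantitative convention exists for score-based reading of such
maps.

## Biometry

The largest predicted head mask over the exam (ties: earliest sweep, then
frame) is the measurement frame. The mask's second central moments give
the equivalent ellipse — a uniform ellipse with semi-axes (a, b) has
covariance eigenvalues (a²/4, b²/4) — and **BPD is the full minor axis**,
2 × semi-minor × spacing. Reading the measurement as 2 × the *full* minor
axis instead would force BPD ≥ HC/π · 2, an anatomically impossible
head, so the semi-minor reading is used. **HC** is the border length of
the same mask: the 0.5-level marching-squares contour of the lightly
blurred (σ = 1 px) indicator, measured in physical coordinates; the
fitted-ellipse Ramanujan perimeter is available as `method = "ellipse"`
for sensitivity analysis. If the mask has several connected components
the largest is measured and the result is flagged.

Frames resized to the network input have anisotropic spacing; rather than
resampling the mask back through the crop/resize transform, the moments
and the contour are computed directly in millimetre coordinates using the
per-axis spacing recorded by `crop_and_resize()` — mathematically the same
measurement without an interpolation step. Physical extent bookkeeping is
exact: out-size × new spacing = crop extent × old spacing, per axis.

Gestational-age regressions are data, not code: a CSV of named polynomial
curves (GA in weeks from a measurement in cm) with validity ranges,
defaulting to classical Hadlock-type coefficients. Out-of-range inputs
warn but still return an estimate.

## Agreement statistics

Implemented from their defining formulas and checked against independent
computations (ANOVA mean squares via `lm`, direct arithmetic) to 1e-8 on
random fixtures: overall percent agreement; Cohen's κ with the marginal-
product chance term, the large-sample z-test against κ = 0, and the
interpretation bands (0–0.2 slight, 0.21–0.4 fair, 0.41–0.6 moderate,
0.61–0.8 substantial, 0.81–1 almost perfect); a one-sample t-test for a
collection of per-fold coefficients; sensitivity/specificity/PPV/NPV
against a positive class; two-way absolute-agreement ICC (single-measure
default, average-measure optional — the variant choice is left open by
convention, and single-measure is the conservative default); Bland–Altman
bias (model minus reference) with 1.96·SD limits; and the mean per-pair
absolute relative error — per-pair, not a ratio of means, because only the
per-pair definition is consistent with percent errors exceeding the
difference of the group means. Placental tables can exclude pairs where
either rater chose *fundal*, since fundal implantation straddles the walls
and confounds anterior/posterior agreement.

## Cross-validation harness

`make_folds()` builds one fold per patient (fold *i* tests patient *i*);
`run_loocv()` trains per fold — seeded as master seed ⊕ fold index, so
folds are independent but the run is reproducible — evaluates on the
held-out patient, and records seven metrics: sensitivity, specificity,
PPV, NPV, Jaccard, pixel accuracy, area error. `select_best()` aggregates
them by mean rank (area error ascending, the rest descending; ties to the
lowest fold), a scale-free reading of "best combination of evaluation
parameters". Frame-level assignments are stored so `audit_folds()` can
assert zero test-frame leakage. `evaluate_holdout()` runs the full
diagnosis on new exams and builds the agreement reports; reference entries
recorded as NA ("unable to report") are excluded and counted.

Whether the 80/20 split should be re-randomized per fold was an open
choice; per-fold seeded re-randomization is used, keeping folds
independent while reproducible.

## Problem sizes used in tests

The suite runs at deliberately small scale, chosen once as sizes a
reviewer can re-run on a laptop CPU: unit tests use 32×32–64×64 networks
and 12-frame sweeps; the learning check trains a base-8, depth-3 U-Net on
300 phantom frames at 128×128 for 10 epochs (validation Dice ≥ 0.8); the
end-to-end recovery test diagnoses 20 oracle-segmented phantoms; the LOOCV
demonstration uses 3 phantom patients at 64×64. `scripts/acceptance.R`
recomputes all headline quantities at these sizes from a single `--seed`.

## Known limitations

* Clinical metric levels (segmentation Jaccard on real scans, κ against a
  specialist, GA-within-14-days rates) require patient data and trained
  clinical weights; nothing in the phantom validates them.
* The classifier thresholds are calibrated to the phantom's geometry
  conventions; a real deployment would re-tune them on annotated exams via
  `classifier_params()`.
* Only frame-level presence enters the map — per-pixel fusion across
  sweeps, 3D reconstruction, and probe tracking are out of scope.
* The placenta previa flag is a referral heuristic; no positive previa
  case exists in the synthetic or clinical evidence base.
* Femur length and abdominal circumference are not measured.
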