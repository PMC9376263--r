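---
title: "Methods: fundus image grading with HOG-PCA features and a GWO-tuned ELM"
author: "fundusDR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fundus image grading with HOG-PCA features and a GWO-tuned ELM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusDR)
```

# The problem

Diabetic retinopathy (DR) is graded from retinal fundus photographs on a
five-level severity scale: no DR, mild, moderate, severe, and
proliferative DR (labelled 1-5 here). `fundusDR` implements a complete
classical (non-deep-learning) grading pipeline -- image normalisation,
hand-crafted gradient descriptors, linear dimensionality reduction, and
a single-hidden-layer network whose input layer is tuned by a
population metaheuristic -- together with the evaluation protocol used
to score it in binary (no DR vs. any DR) and five-class modes.

# Pre-processing

`preprocessFundus()` applies four deterministic steps: read the RGB
array, collapse to grayscale, stretch contrast, and resize to a square
grid (255 x 255 by default).

* **Grayscale.** ITU-R BT.601 luminance weights (0.2989, 0.5870,
  0.1140), the `rgb2gray` convention shared by most image toolboxes.
  Intensities live in [0, 1] internally regardless of input bit depth.
* **Contrast.** A linear quantile stretch: the `lowTail` quantile maps
  to 0 and the `highTail` quantile to 1, values outside are clipped
  (defaults 0.01/0.99, the usual 1% saturation of `imadjust`-style
  adjustment). The map is monotone, so pixel ordering -- and hence
  gradient orientation structure -- is preserved. A constant image has
  no defined stretch and is returned unchanged with a warning.
* **Resize.** Separable bicubic (Catmull-Rom) resampling with
  pixel-centre alignment and replicated edges. The kernel's weights
  sum to one, so constants are preserved and a same-size resize is the
  identity; because cubic kernels can overshoot near edges the result
  is clipped back to [0, 1]. The exact stretch algorithm and
  interpolation kernel are classical defaults rather than forced
  choices, so both are exposed as arguments.

# HOG descriptors

`hogDescriptor()` computes a dense Histogram of Oriented Gradients:
centred differences ([-1, 0, 1]) give per-pixel gradient magnitude and
orientation; orientations are folded to [0°, 180°) (unsigned);
magnitudes vote into 9 orientation bins per 8 x 8-pixel cell with
bilinear interpolation between the two nearest bin centres (circular
across the fold); 2 x 2-cell blocks slid with a one-cell stride are
L2-Hys normalised (L2-normalise, clip at 0.2, renormalise) and
concatenated row-major over blocks, then cells, then bins.

This geometry is the unique common parameterisation for which a
255 x 255 image yields exactly 32,400 features: 31 x 31 cells give
30 x 30 block positions of 2 x 2 x 9 = 36 entries each, and
`hogLength()` provides the closed form
`(floor(side/8) - 1)^2 * 36`. Trailing pixels that do not fill a cell
(7 of 255 per axis) are ignored, as in the standard extractors. All
knobs are configurable through `HOGParams()`. Cell-level spatial
interpolation is deliberately omitted (votes go to one cell only);
with block overlap already smoothing responses this is the common
default in MATLAB-style extractors.

The descriptor is exactly invariant to a global intensity offset
(gradients are unchanged) and invariant to positive intensity scaling
up to the normalisation clip.

# PCA

HOG matrices are wide (tens of thousands of columns) but short
(hundreds of rows), so `fitPCA()` eigendecomposes the N x N sample
Gram matrix rather than taking an SVD of the full matrix, and recovers
feature-space components as `t(Xc) u / sqrt(lambda)`. At most N - 1
components carry positive variance; generic full-rank data attains
exactly N - 1, reproducing e.g. a 950 x 949 score matrix from 950
images. Numerical choices:

* rank cutoff: eigenvalues below `lambda_1 * N * eps * 100` plus an
  absolute floor at the square of the centring rounding noise are
  treated as zero -- a matrix of identical rows reports rank 0 instead
  of numerical dust;
* sign convention: each component's largest-magnitude loading is made
  positive, so fits are bit-reproducible;
* `fitOn = "all"` (default) fits the basis on every row before any
  train/test split. This replicates the reference experimental
  protocol exactly -- including its information leakage from test rows
  into the basis. `fitOn = "train"` is the clean alternative and is
  what the package's own parameter-recovery tests use where leakage
  would matter.

# The ELM and its GWO-tuned variant

An Extreme Learning Machine is a single-hidden-layer feed-forward
network: input weights `w` (L x n) and biases `b` (length L) are
random -- uniform in [-1, 1] and [0, 1] respectively -- the hidden
layer is `H = sigmoid(X w' + b)`, and the output weights solve the
linear system `H rho = T` for one-hot targets `T` in closed form,
`rho = pinv(H) T`. The pseudoinverse uses SVD with a relative cutoff
of 1e-12; no ridge term by default (a `ridge` argument exists but the
plain Moore-Penrose solve is the reference formulation). One-hot
coding is 0/1; prediction takes the argmax of the m class scores with
ties to the lowest class index. With L = N and generic data the
network interpolates its training set exactly -- a useful sanity
property that the tests assert.

Gray Wolf Optimization is a population metaheuristic: candidate
solutions ("wolves") move toward the three best solutions found so far
(alpha, beta, delta) under stochastic coefficient vectors
`A = 2 a r1 - a` and `C = 2 r2`, with `a` decaying linearly from 2 to
0 over the run -- from exploration to exploitation. Per leader k:
`D_k = |C_k X_k - x|`, `X'_k = X_k - A_k D_k`, and the new position is
the mean of the three `X'_k`. Implementation decisions where the
formulation leaves room:

* positions are clipped to the search box after each update;
* `r1`, `r2` are drawn independently per dimension, per leader, per
  agent, per iteration;
* leaders are updated only on strict fitness improvement (ties keep
  the earlier agent), which makes the alpha-fitness trace monotone
  non-decreasing -- asserted on every run in the tests;
* maximisation is the native sense; minimisation negates.

`trainGWOELM()` couples the two: each agent is the flattened
`(w, b)` pair -- layout `w` row-major then `b`, length `L (n + 1)` --
searched inside the mixed box ([-1,1] on weight coordinates, [0,1] on
biases). The fitness of an agent is the training-set classification
accuracy of the ELM it encodes (the output weights are re-solved in
closed form at every evaluation). Whether the original formulation
scored agents on training or held-out data is ambiguous; scoring on
test data would leak, so training accuracy is the default and an MSE
variant (`fitness = "mse"`, the squared-error objective) is available.
After the run the alpha is decoded verbatim -- the final model's
`(w, b)` equal `decodeAgent(bestPosition)` bit for bit -- and `rho` is
recomputed once from it.

# Evaluation

Seven measures are reported as percentages (2 decimals, rounded half
away from zero; full precision kept internally): accuracy, precision,
recall, specificity, Matthews correlation coefficient, F-measure, and
G-mean. G-mean here is the geometric mean of recall and precision
(matching the reference formulation), not the more common
recall-specificity variant. Zero denominators flag the affected metric
as `NA` with a warning, never a silent zero.

For K >= 3 classes the K x K confusion matrix is reduced one-vs-rest
(`ovrCounts()`), the four counts are micro-summed over classes, and
the binary formulae are applied to the sums -- except accuracy, which
is the class-averaged one-vs-rest accuracy. For a balanced matrix with
n observations and e errors these identities follow and are asserted
as properties: micro precision = micro recall = (n-e)/n, specificity =
(Kn-n-e)/(Kn-n), accuracy = (Kn-2e)/(Kn). This scheme is the unique
simple aggregation that reproduces every published cell of the
reference result tables; the binary confusion counts behind those
tables are recovered -- and shown to be unique -- by exhaustive integer
search in the test suite.

The experimental protocol (`stratifiedSplit()`,
`runExperimentGrid()`): a stratified 80/20 split (per-class floor
allocation, remainder to the largest fractional parts -- a balanced
5 x 190 set splits 152/38 per class; counts 168/25/168/93/62 split
412/104), binary relabelling that pools grades 2-5 as "disease", and a
hidden-node sweep of 100 to 300 in steps of 25. Two datasets x two
modes x nine node counts = 36 experiment cells, each seeded as
`seed + cell` for reproducibility. The per-class 152/38 figures force
a stratified split; the reference text does not state stratification
explicitly, but no unstratified split reproduces them.

# The synthetic generator

Real fundus datasets cannot be redistributed with the package, so all
tests and examples run on synthetic inputs.

`makeFundusImage()` draws a stylised retina: circular field of view, a
radial intensity falloff, a bright optic disc, dark random-walk
vessels, and grade-dependent lesions -- small dark dots
(microaneurysm-like) and brighter, larger blobs (exudate-like). Counts
are Poisson with expected values per grade of (0, 4, 10, 20, 35) dark
and (0, 2, 6, 12, 20) bright; grade 1 has none, and the expected
lesion burden increases strictly with grade (asserted over 50 seeds).
The default side of 510 pixels makes the resize step non-trivial.
The morphology is deliberately crude: the generator exists to exercise
the pipeline and provide a controllable class signal, not to be
clinically realistic. Passing tests therefore demonstrate mechanical
and statistical correctness of the pipeline, not clinical performance
on real retinas.

`makeFeatureDataset()` samples class c from an isotropic unit-variance
Gaussian centred at class-specific means placed so every pairwise mean
distance equals `separation` (in within-class SD units; scaled unit
vectors, which requires `nFeatures >= nClasses`). `separation = 0` is
chance; 10 is trivially separable; 3 is the "moderate" default used
where tests need overlapping classes. Rows are shuffled under the
given seed.

# Problem sizes and runtime choices

The test suite runs everything at desk scale: the full-width PCA check
uses a 950 x 32,400 random matrix (the Gram-side decomposition handles
it in seconds), optimizer properties use 50 agents x 100 iterations on
a 5-dimensional sphere over 20 seeds, the hybrid-vs-baseline
comparison uses 190 samples per class (the reference per-class count)
with 10 agents x 20 iterations at L = 100 over 20 paired seeds, and
the end-to-end smoke run uses 20 images per grade at 510 x 510 with
10 agents x 10 iterations. A full-budget run (50 agents, 100
iterations, L swept 100-300) on features of this size takes minutes
per cell rather than seconds and is left to the user.

On the hybrid-vs-baseline comparison specifically: with 760 training
rows, 10 isotropic informative features and separation 3, the plain
ELM already sits at the dataset's achievable accuracy, so tuning the
input layer improves the mean test accuracy only slightly (~1 point)
while the paired per-seed ordering holds in roughly three quarters of
runs rather than uniformly. The package reports this comparison as
measured; an independent re-implementation of the whole loop
reproduces the same rates, so the behaviour reflects the statistical
regime, not the implementation.

# Known limitations

* No retina-specific masking (field-of-view cropping, vessel
  enhancement): the pre-processing is the generic four-step chain.
* `fitOn = "all"` PCA replicates a leaky protocol by design; use
  `fitOn = "train"` for honest generalisation estimates.
* Accuracy as a fitness is coarse (steps of 1/N), so GWO progress
  stalls on plateaus when the hidden layer can interpolate the
  training set; keep L well below N or use the MSE fitness.
* ROC/AUC curves and cross-validation are out of scope; the protocol
  is a single stratified split.
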