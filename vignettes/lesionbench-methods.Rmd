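---
title: "Methods: weakly dependent lesion features, the classifier bench, and the explanation layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weakly dependent lesion features, the classifier bench, and the explanation layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: the feature
definitions and the reading choices behind them, the classifier
configurations, the metric conventions, how the explanation layer is
computed and why it is exact, what the synthetic generator does and does
not emulate, and the numerical decisions that a maintainer would otherwise
have to reverse-engineer.

## 1. The two feature classes

A lesion sample is an 8-bit grayscale image `I` (M×N) plus a binary mask
`B` of identical size drawn by clinical experts, with the label coding
0 = malignant, 1 = benign. The masked image `ROI = I ⊙ B` zeroes the
background. The gray range is tiled by eight inclusive 32-level bins
`[0,31], [32,63], ..., [224,255]`; no gaps, no overlap.

Two bin-occupancy vectors are computed:

* `CHk`: fraction of **all M·N cells** of the masked image with intensity
  in bin k (full-frame normalization; the background zeros therefore land
  in bin 1);
* `Ck`: fraction of **in-mask pixels** with intensity in bin k
  (lesion-area normalization, `S = Σ B`).

Both sum to one, and for bins 2..8 the counts coincide:
`CHk·M·N = Ck·S`. Bin 1 differs by exactly the background-zero count.
This is what makes the pair *weakly dependent*: identical bin tallies,
different normalizations and background handling.

Three reading decisions were required and are fixed here:

* **The last bin covers [224, 255].** Any other lower bound would make
  bins overlap and the histogram partition sum exceed one; every bin spans
  exactly 32 levels.
* **CHi is normalized by the full frame, with background zeros counted in
  bin 1.** Normalizing the masked histogram by the lesion area instead
  would make CHi and Ci identical, contradicting their stated role as
  distinct, complementary classes. Under the full-frame reading CH1 also
  carries a (crude) lesion-size signal.
* **Ci counts pixels, not intensity sums.** Only the count reading keeps
  `Ci ∈ [0, 1]` and matches its definition as an area ratio.

Whether `M·N` should instead be a cropped bounding box is not decidable
from the definitions; the full-frame reading is adopted, and the
alternative would only rescale all CHi by a common factor.

Practical conventions: masks stored as 0/255 images are binarized at
"nonzero = lesion"; several masks for one image are united; 3-channel
inputs collapse by Rec. 601 luma weights and round back to 8-bit. Lesion
segmentation itself is out of scope — masks are inputs, never computed.

### Numerical form

Bin sums are formed over **integer counts** and divided once by the
normalizer. This is mathematically identical to summing the normalized
histogram term by term but keeps the count identities exact in floating
point: the package's features equal an independent nested-loop tally
bit-for-bit, while `ΣCH = 1` holds to 1e-12 (the sum of eight correctly
rounded rationals need not be exactly 1.0 in binary).

## 2. The classifier bench

Four classifiers run on the 16-column table (or either 8-column class):

| kind | configuration | seed |
|---|---|---|
| `rf` | random forest, 200 trees, Gini impurity | 0 |
| `xgb` | boosted trees, learning rate 0.02, depth 3, 100 rounds | 2 |
| `gbc` | boosted depth-1 stumps, learning rate 1.0, 100 rounds | 0 |
| `lasso` | L1 logistic regression, standardized features, balanced class weights, C tuned on {0.001..1000} by stratified 5-fold CV on ROC-AUC | 0 |

Both boosting configurations are served by one backend (xgboost). The
`friedman_mse` split criterion named in the scikit-learn boosting family
has no direct equivalent there; it maps to the backend's second-order gain
criterion. The scikit-learn-style `C` translates to the glmnet scale as
`lambda = 1 / (C · n)` (sum-loss + (1/C)·penalty versus mean-loss +
lambda·penalty); CV ties resolve toward the smallest C, i.e. the stronger
regularization, matching a first-hit scan of the ascending grid. Class
weights `n / (2·n_class)` implement "balanced". Standardization uses
training statistics only, recomputed inside each CV fold.

### The metric chain

All evaluation flows through the 2×2 confusion matrix with the malignant
class (0) indexed first, printed `[[n00 n01][n10 n11]]`:

* accuracy `(n00 + n11) / n`;
* **F1 with malignant as the positive class**, `2·n00 / (2·n00 + n01 +
  n10)`. This convention is forced by the shipped reference results: the
  RF row `[[48 2][3 109]]` prints F1 = 0.950 = 96/101, which only the
  malignant-positive reading produces (benign-positive would give 0.978).
  The two lasso reference rows are the exception — their printed F1 values
  match only the benign-positive reading, which the reference-data
  documentation records;
* rank-based (Mann–Whitney) AUC with **benign as positive** (a pure
  convention; the reference table cannot discriminate the two readings);
* the McNemar statistic `(n01 − n10)² / (n01 + n10)` on the confusion
  off-diagonals, **without** continuity correction — the only variant that
  reproduces the six non-lasso reference χ² cells (a continuity-corrected
  option exists but is not the default). The two lasso χ² cells follow no
  off-diagonal formula we can identify and are retained verbatim as
  reference, never recomputed or asserted.

Reference values are printed truncated (3 decimals for accuracy/F1, 2 for
χ²); agreement checks therefore use one unit of printed precision (0.002
and 0.01 respectively). The reference metrics are described as CV means,
yet they are exactly the arithmetic of the printed hold-out matrices; the
bench sidesteps the ambiguity by always reporting hold-out and CV-mean
metrics side by side under distinct labels.

Splitting is stratified 75:25 with per-class test counts
`floor(n·f + 0.5)` (649 records give a test set of 162–163). CV folds are
stratified with per-class remainders placed into the currently smallest
folds, so overall fold sizes differ by at most one. The splitter seed
defaults to 0 and is recorded in every artifact.

### Importance selection

Tree models report split-impurity importance normalized to sum 1; the
lasso reports |standardized coefficient| normalized the same way. A
feature is selected iff its weight **strictly exceeds 0.125**, the mean of
8 equal weights — so a perfectly flat profile selects nothing. With 16
columns the same absolute threshold is deliberately kept (it is a fixed
constant of the method, not 1/p).

## 3. The explanation layer

### Exact tree Shapley

Attributions explain the model's benign-direction score: the benign vote
fraction for the forest, the log-odds margin for boosting, the linear
predictor for the lasso. Positive values push toward benign (1), negative
toward malignant (0).

For a tree ensemble the coalition game is the standard path-cover one:
evaluating `v(S)` follows a split when its feature is in `S` and averages
both children weighted by *cover* (training weight through each node)
otherwise. The weight a leaf receives under `v(S)` factorizes over the
distinct features on its path — per feature, a product of split
indicators if the feature is in `S`, or of child/parent cover ratios if
not. Each leaf therefore defines a multilinear game whose Shapley values
have a closed form; a subset-size polynomial built in `O(depth)` per leaf
and unwound once per path feature gives exact attributions in
`O(leaves · depth²)` per record and tree (compiled, `src/treeshap.cpp`).
Summing leaves and trees is exact by linearity. Two consequences are
tested rather than assumed: agreement with full `2^8`-subset enumeration
to 1e-9, and local accuracy (`Σφ + base = score(x)`) on every explained
record to 1e-6 (the forest is exact to machine precision; the boosting
backend reports float32 leaf values, which caps agreement near 1e-7).

Covers come from routing the model's own training data: bootstrap in-bag
counts per tree for the forest, unit weights for boosting. The boosting
intercept (base margin) is recovered at fit time by subtracting the leaf
sum from a predicted margin.

The lasso uses the closed linear form `φ_j = β_j (z_j − mean z_j)` over
the standardized training background. A seeded permutation-sampling
estimator is available for any model kind as a fallback; it is Monte
Carlo, not exact, and is never used where an exact route exists.

The global ranking orders features by mean |SV| over the explained
records; each feature lands in the class list its values push toward
(sign of the correlation between feature value and attribution; a
zero-variance column falls back to the sign of its mean attribution).
Signed scores keep the direction visible: negative = malignant-driving.

### Tabular LIME

One instance at a time: features are discretized into quartile bins of the
background (training) data; perturbed samples draw a bin per feature from
the background marginals and a uniform value within the bin's range; the
interpretable representation is the "same bin as the instance" indicator.
A ridge regression (penalty 1, unpenalised intercept) of the model's
benign probability on the indicators, weighted by
`exp(−d² / (0.75·√p)²)` on binary distance, yields signed local weights;
sign assigns the class exactly as above. Defaults: 5000 perturbations,
seeded; the sample count and seed are free parameters because the method
itself fixes neither. The first perturbed sample is the instance itself.

Which test instance the published single-instance probabilities describe
is not identifiable, so instance identity is always an explicit, labelled
input (`lime_instance` in the pipeline, `--instance` on the CLI), and
published LIME probabilities are never acceptance quantities.

### Agreement

`rank_agreement` intersects, per class, the top-k sets (default k = 3,
the depth of the published per-class lists) of LIME, SHAP, and the top-k
impurity features, reporting all pairwise and the three-way
intersections; `common_across_classifiers` intersects one explainer's
per-class sets across classifiers, mirroring the published boldface
convention. Rankings are treated as ordinal only.

## 4. The synthetic cohort generator

The generator is fixture engineering, clearly labelled as such: the
method was developed on real ultrasound images, and no generative model
accompanies it. The generator's job is to produce a *learnable, correctly
oriented* bin-occupancy contrast, not realistic ultrasound physics.

Defaults (the study conditions of every full-scale test): 128×128 frames;
background speckle N(40, 10) clipped to 8 bits; benign lesions as smooth
ellipses with hypoechoic interiors N(70, 12) — gray band 64..95 is bin 3;
malignant lesions as star-convex shapes `r(θ) = r0(1 + 0.35·P(θ))` with
`P` a 3–8-harmonic random-phase sum normalized to unit peak (spiculated
but non-self-intersecting), brighter interiors N(120, 25), and
Poisson(6)-many microcalcification discs (radius 1–2 px, intensity
≥ 224 = bin 8) placed with a minimum separation of 6 px so the spots stay
distinct components. Base radius is 0.15–0.28 of the frame side; a lesion
below 1% of the frame area is regrown with a 1.3× radius, at most 10
times. Class sizes default to 211 malignant / 438 benign, the composition
of the reference image collection. Cohort seeds derive per-sample
sub-seeds, so cohorts are reproducible bit for bit.

Design notes: speckle is clipped Gaussian rather than Rayleigh — nothing
downstream depends on speckle statistics, only on bin occupancy; there is
no point-spread function, attenuation or shadowing. Consequently, passing
tests demonstrate that the pipeline recovers a known, well-separated
contrast (bright bin 8 ⇒ malignant, bin 3 ⇒ benign) — they say nothing
about accuracy on real ultrasound, where class overlap is severe. On the
default cohort the classes are nearly separable, so hold-out accuracies
sit at or near 1.0 by construction.

One scale effect is worth recording: the bright-bin features reach the
malignant top-3 of the forest's SHAP ranking reliably at the full 211/438
scale, which is where that property is asserted; at desk scale (e.g.
100/100) mid-gray interior bins can outrank them, and only the direction
(bright bins on the malignant side) is stable.

## 5. Problem sizes, degenerate inputs, known limitations

Test and acceptance runs use: 100 random image/mask pairs up to 64×64 for
oracle equivalence; depth-≤3 ensembles on 8 features against full 2^8
Shapley enumeration; three full-size 211/438 cohorts for end-to-end
recovery; 120 malignant lesions for the calcification-count property.
The whole suite runs in well under a minute on one CPU.

Degenerate inputs are defined, not left to chance: an all-zero mask is an
"empty lesion" error; a single-class table refuses to split or train;
constant feature columns are logged, not fatal; zero discordant confusion
cells define χ² = 0 with a warning; an absent positive class defines
F1 = 0 with a warning; a zero-variance LIME background is an error.

Known limitations: no real-image benchmark ships with the package (the
reference confusion matrices are inputs, and BUSI itself is external); the
boosted-stump configuration places split thresholds directly at training
values, so a held-out extreme inside a wide class gap can fall on the
wrong side (the forest's mid-gap splits do not share this quirk); LIME
weights carry Monte Carlo noise at any finite sample count; and the exact
Shapley route applies to the tree and linear models only — other model
families would fall back to sampling.
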