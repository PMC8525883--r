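---
title: "Models and methods behind neopredict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neopredict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

neopredict predicts neurodevelopmental outcome (Bayley-III cognitive,
language or motor scale scores, 40–160, mean 100, SD 15) in very preterm
infants from four kinds of term-equivalent-age data: a functional brain
connectome, a structural brain connectome, a DWMA (diffuse white matter
abnormality) feature vector, and a perinatal clinical vector. This vignette
explains each stage's model and assumptions, the tunable parameters, what
the synthetic cohort generator does and does not emulate, and the numerical
and design choices a maintainer would want to know about.

## Feature quantification

**DWMA.** Diffuse white matter abnormality is diffuse T2 hyperintensity in
cerebral white matter. Given a T2 intensity volume and disjoint white
matter / gray matter / CSF masks, a voxel counts as DWMA when it lies in
cerebral tissue (white ∪ gray) and exceeds `mean + α·SD` of cerebral-tissue
intensity. Because a single optimal α transfers poorly across acquisition
protocols, the feature vector sweeps α over 1.4–2.0 in 0.1 steps and
records, at each α, DWMA volume normalized by total white matter volume;
the detected volume is therefore non-increasing in α, and the mask is
invariant to affine intensity rescaling. Four volumetric confounders are
appended: white matter, gray matter, CSF and total cerebral (wm + gm)
volume. The feature vector is fixed at eleven elements, while seven
thresholds plus three tissue volumes make ten; we complete it with cerebral
volume — the natural companion of the white-matter normalizer — and flag
the choice here because the remaining element is not stated anywhere we
could find.

**Connectomes.** The functional connectome is the Pearson correlation
matrix of ROI-level BOLD time series on a 223-node neonatal functional
parcellation: unit diagonal, entries in [−1, 1], positive semidefinite by
construction. Raw correlations are used; the question of thresholding or
Fisher-transforming negative edges has no universally accepted answer, and raw
values are the least-committal choice. The structural connectome on the
90-node anatomical parcellation averages fractional anisotropy per tract
(mean over the tract's voxels) and then over all tracts joining a node
pair; unconnected pairs get 0, the diagonal is 0, and FA lives in [0, 1].
Tract tables arrive long-format (`tract_id, roi_a, roi_b, fa` per voxel);
self-connecting tracts are dropped with a warning.

**Harmonization.** Site and scanner differences are removed with ComBat,
the parametric empirical-Bayes location/scale model: features are
standardized against the batch-size-weighted grand mean and pooled residual
variance; per-batch location (γ) and scale (δ) estimates are shrunk with
moment-matched normal / inverse-gamma priors via the standard fixed-point
iteration; effects are removed and the grand scale restored. Our
implementation deliberately uses one variance normalization (1/n) for both
the pooled variance and the per-batch δ estimates, so two statistically
identical batches pass through at machine precision and a degenerate
across-feature prior (all features alike) applies no shrinkage. The test
suite pins elementwise agreement with the sva reference implementation.
Note one honest property of any EB ComBat: location shrinkage perturbs the
per-feature pooled mean at the sampling-noise scale (∼10⁻⁴ at n = 200 per
batch); exact mean preservation holds only in the no-shrinkage cases.
Connectome matrices are harmonized on vectorized upper-triangle edge
features and mirrored back, keeping one code path for both modalities.

## Balancing and augmentation

Supervised training sets are small and skewed toward low-risk infants.
Training folds are balanced by binning scores into five severity bins
(<70, 70–79, 80–89, 90–100, >100; boundaries chosen so the five reported ranges
partition [40, 160], with 100 kept in the fourth bin) and
synthesizing into deficient bins: a seed sample from the bin and its k
nearest original neighbours (k = 5 by default, clamped to bin size − 1) are
combined with flat-Dirichlet simplex weights applied identically to every
modality tensor and to the score. Convexity preserves all modality
invariants and keeps the synthetic score inside the parents' range.
Neighbour distance is Euclidean on the concatenation of the flattened
modalities, each block z-scored so no modality dominates; the search stays
inside the seed's bin so synthetic scores stay near it — both choices are
ours, since the sources are ambiguous about the distance space and about
cross-bin neighbours. Phase two keeps synthesizing round-robin into the
smallest bins until the set reaches ten times its original size. Synthetic
samples are training-only: the evaluation harness refuses any synthetic
record outright, and splits are drawn before augmentation.

## The fusion network

Each modality has a channel. Connectome channels pass the adjacency matrix
— functional values mapped by (x+1)/2, structural unchanged, bilinearly
resampled to the extractor's square input (224 default), replicated to 3
channels and standardized by fixed constants (x−0.5)/0.25 — through a fixed
16-convolution / 5-pool extractor in the classic VGG-19 layout
(64,64 | 128,128 | 256×4 | 512×4 | 512×4, 3×3 kernels, ReLU, 2×2 max
pools). Extractor weights are frozen in every phase; the default source is
a seeded He-scaled random draw, which keeps the package self-contained —
ImageNet-trained weights can be supplied where fidelity to a pretrained
extractor matters, and the difference is consequential for interpretability
(below). The flattened extractor output (25088 at full width) feeds two
trainable fully connected blocks (FC → batch norm → ReLU → dropout 0.2) of
widths 64 and 16; tabular channels (DWMA 11, clinical 72) use the same two
blocks directly. The four 16-dimensional embeddings are concatenated in a
fixed order (functional, structural, DWMA, clinical; 64 values), pass an
8-unit fusion block, and end in a 2-class softmax (risk classification,
high risk = score ≤ 90) or a single linear unit (score regression). The
layer table lists no activation for the FC blocks; we use ReLU throughout,
consistent with the pretraining description, including after the fusion
batch norm.

Inputs are scaled with constants fitted on the training split only:
tabular channels are z-scored per feature (the DWMA vector mixes ratios of
order 0.1 with volumes of order 10⁵ mm³ and is unlearnable otherwise);
connectome extractor features are min-max scaled to [0, 1] per feature,
matching the autoencoder pretraining convention so transplanted encoder
weights see identically scaled inputs.

## Training

**Unsupervised pretraining.** The connectome channels' FC blocks are
pretrained as a stacked sparse autoencoder on unlabeled extractor features:
greedy layer-wise, ReLU encoder, mirrored sigmoid-output decoder,
mean-squared reconstruction error plus a sparsity penalty, mini-batch Adam.
The published form of this loss is sometimes written with a leading minus sign, which would
make it a quantity to maximize; we treat that as a typo and minimize the
positive MSE. The sparsity penalty admits several standard forms;
the default is an L1 penalty on hidden activations with weight 10⁻⁴, with a
KL-divergence alternative (target activation 0.05) available — both are
standard. The learning rate may be fixed or selected from
{0.001, 0.01, 0.1, 0.5} by held-out reconstruction loss; 50 epochs. Only
the connectome channels are pretrained; DWMA and clinical blocks are
randomly initialized (descriptions of such procedures are sometimes ambiguous on this point; the
contrary; the explicit channel-level statement wins).

**Supervised fine-tuning.** All FC blocks and the fusion head are trained
with mini-batch Adam: learning rate 0.01 decremented by lr/epochs each
epoch, batch size 4, 50 epochs, dropout 0.2; cross-entropy loss for
classification, mean absolute error for regression (the training-set score
mean is absorbed into an output offset so the linear unit learns
deviations). Early stopping is a tolerance rule — validation loss changing
by less than 10⁻⁶ for 5 consecutive epochs halts training — since exact
loss equality never happens in floating point while batch-norm running
statistics are still drifting. The weights with the best validation loss
are returned; whether "best" meant last-epoch or best-validation in the
original procedure is not stated, and best-validation is the conservative
reading. An architecture search over FC depth 1–4 and shared width
{8, 16, 32, 64} by repeated 2-fold validation is provided
(`grid_search_architecture`); the shipped defaults (64, 16) are the
selected architecture.

## Interpretability

For tabular channels, feature importance is the mean absolute partial
derivative of the high-risk softmax output with respect to each input
feature, across evaluation subjects, in evaluation mode. For connectome
channels, Grad-CAM: gradients of the high-risk output at the last
convolutional layer's feature maps are global-average-pooled into per-map
weights α_k; the heatmap ReLU(Σ α_k A^k) is bilinearly rescaled to
adjacency size, symmetrized as (H+Hᵀ)/2 because connections are
undirected, and min-max normalized after those steps so a non-zero map
attains exactly 1. Cohort-level results average the per-subject maps and
mean absolute gradients — the aggregation is our choice. All gradients are
validated against central finite differences on miniature networks.

A practical warning from our own validation: with seeded-random extractor
filters, Grad-CAM loses its class-discriminative character. The heatmap is
a sum of activation maps weighted by global scalars, and random channels
are not feature-selective, so the map collapses toward an input-energy map
dominated by the brightest constant structure — for a functional adjacency
image, its unit diagonal. Our planted-edge recovery experiment
(`experiment_recovery`) recovers 0 of 5 planted edges in the top-10
connections under random filters even though the spatial plumbing is
verified exact (a bright-spot probe localizes to the correct cell with a
±2-map-cell point spread, and α_k matches finite differences to <10⁻³).
Grad-CAM interpretability should therefore be trusted only with a
pretrained, feature-selective extractor. Gradient ranking of tabular
features has no such dependence: the two continuous informative clinical
features rank at medians 1 and 2 of 72 across seeds; a binary informative
feature ranks far lower and unstably (median 45), as binary indicators
carry less and noisier gradient mass through the network.

## Evaluation

Nested cross-validation: per repeat, five stratified folds (stratified by
risk class, so every test fold can compute AUC); fold f is the test set
(20%), the next fold validation (20%), the rest training (60%); every
subject is tested exactly once per repeat; 50 repeats at full scale.
Augmentation, input scaling and model selection happen strictly inside the
training/validation portions. Metrics: sensitivity (high-risk recall),
specificity, balanced accuracy (their mean, in percent), AUC by the
rank-sum method with ties averaged (cross-checked against pROC);
regression reports Pearson r, MAE, and the sample SD of absolute errors.
Summaries are mean ± SD over all fold×repeat evaluations. Model
comparisons use the classic two-sided two-sample Student's t-test;
demographic 2×2 tables use Pearson's chi-squared without continuity
correction, which reproduces the reference sex-by-risk p-values (0.906,
0.7025, 0.6581) exactly.

## The synthetic cohort generator

No public cohort exists, so every claim the package tests is exercised on
simulated data with planted ground truth. A latent standard-normal risk z
drives the score (score = 100 − g·z + ε, ε ~ N(0, σ²), clipped to
[40, 160]; defaults g = 12, σ = 10, giving ≈26% high-risk — close to a
25/72 split). Functional matrices are sampled as T-frame time series from
a covariance whose planted edges shift with z, then correlated — so every
simulated matrix is a genuine correlation matrix (PSD repair shrinks an
infeasible planted effect with a warning). Structural matrices add
z-scaled effects on a fixed sparse FA pattern (planted edges sit on a
mid-range base so effects can move both ways before clipping). The DWMA
profile decays in α and scales with z; clinical vectors mix continuous and
binary features with an informative subset loaded on z; optional per-batch
shift/scale on edges emulates site effects (and may push functional
matrices off the exact correlation manifold — precisely what harmonization
removes); optional per-modality latent distortion (z_m = z + d_m,
d_m ~ N(0, τ²)) makes the modalities complementary noisy views rather than
redundant copies. The generator does not attempt biophysically realistic
BOLD or diffusion signals, spatial autocorrelation of edges, realistic
clinical covariance, or raw image volumes (DWMA image tests use small
hand-countable volumes); passing tests demonstrate the pipeline's
correctness and statistical behaviour under a known truth, not performance
on real infant cohorts.

## Reduced-scale study conditions

Desk-scale experiments use 120-subject cohorts, 32-ROI "functional" and
24-ROI "structural" parcellations, T = 120 frames, and a reduced-width
extractor profile (one eighth the channel widths, identical
16-conv/5-pool structure). The planted-signal recovery experiment plants
five functional edges (effect 0.25 per unit z) separated pairwise by more
than the Grad-CAM point-spread width — a recovery study that plants sources
closer than the instrument's resolution is ill-posed — and three
informative clinical features (indices 5, 23 continuous, 48 binary); each
channel is probed with a model in which that channel carries the cohort's
outcome signal, because a network offered an easier alternative modality
sidesteps the probed channel and leaves its weights uninformative. It uses
the canonical 224 extractor input, keeping 14×14 last-conv resolution.
The fusion-ordering experiment uses modality noise τ = 0.8, structural
edge noise 0.06 and a 112 extractor input — calibrated so the four
channels are comparably informative and no modality dominates, the regime
in which fusing complementary views is beneficial — plus SSAE pretraining
on a simulated 257-subject unlabeled cohort, mirroring the two-cohort
transfer-learning design. Augmentation is exercised by its own contract
tests rather than inside the ordering experiment, purely to keep the
experiment's compute proportionate. At these sizes the full test suite and
the reproducibility script each run in minutes on one CPU.

## Known limitations

Grad-CAM with random fixed filters is descriptive of input energy, not
class evidence (see above). Fold-level AUC at n = 120 carries intrinsic
sampling noise (test folds of 24 with ≈7 high-risk subjects give AUC
standard errors near 0.12), so single-fold numbers are not interpretable —
only fold×repeat means are reported. Batch-size-4 optimization with batch
norm is noisy; repeat-level means of the fusion model still fluctuate
visibly. The clinical encoder supports continuous z-scoring and integer
level codes only; no multi-column dummy coding (the 72-feature budget is
pinned). Multi-task prediction across the three subtests is out of scope.
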