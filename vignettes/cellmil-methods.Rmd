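---
title: "Weakly supervised single-cell expression from spot-level spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised single-cell expression from spot-level spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Sequencing-based spatial transcriptomics (Visium-style) measures the whole
transcriptome, but only at barcoded capture spots that each cover roughly
10–20 cells. Histology images, in contrast, resolve individual cells. cellmil
treats this mismatch as a multiple-instance learning (MIL) problem: each spot
is a *bag*, the cells detected inside it are *instances*, and the only label
available during training is the bag-level expression vector. A shared
instance-level scorer $f_\theta$ maps a cell's image embedding
$h_i \in \mathbb{R}^d$ to a non-negative vector of per-gene scores, and the
bag prediction is the mean over the spot's $k_s$ cells,

$$\hat{y}_s = \frac{1}{k_s} \sum_{i=1}^{k_s} f_\theta(h_i),$$

which emulates the physical measurement (a spot pools its cells' transcripts).
Because the mean is permutation invariant and differentiable, $f_\theta$ can
be trained end-to-end from spot supervision alone, and after training it is
applied to *individual* cells to produce single-cell expression scores.

The image encoder is deliberately pluggable: any $N \times d$ matrix aligned
to the cell table works (a self-supervised network, transfer-learning
features, one-hot type encodings, or the synthetic encoder used in the
simulations). Training such an encoder is outside this package's scope.

## Model and losses

$f_\theta$ is a fully connected network with three hidden layers of width
256 (ReLU; the activation is not dictated by the method and ReLU is the
standard choice) and a softplus output, so every instance-level score is
non-negative. Two objectives are implemented:

* **MSE on preprocessed expression.** Spot vectors are library-size
  normalized and log-transformed, $y^p_j = \ln(1 + s\, y_j / \sum_j y_j)$
  with $s = 10^4$, then each gene is scaled to a similar range by a robust
  scaler so all genes contribute to the loss. The loss is
  $\mathcal{L}_{mse} = \frac{1}{SG}\sum_{ij} (\hat{Y}^p_{ij} - Y^p_{ij})^2$.
  A subtlety: a median-centred robust scaler makes roughly half of the
  targets negative, which a softplus-activated scorer can never reach — in
  our experiments training then plateaus far from the attainable optimum.
  The training pathway therefore fits the scaler *without centring*
  (divide by the interquartile range only), keeping targets non-negative and
  reachable. `robust_scale()` itself defaults to the full centre-and-scale
  transform; the general operation and its inverse are exposed and tested.
  The scaler is fitted on the training split only (and per slide when
  several slides are stacked) and its inverse is applied at prediction time,
  so reported cell scores live on the log-normalized expression scale.

* **Negative binomial likelihood on raw counts.** Counts are modelled as
  NB with mean $\mu_{ij} = l_i \hat{Y}_{ij}$ and gene-wise inverse
  overdispersion $\alpha_j$ (variance $\mu + \mu^2/\alpha$);
  $\mathcal{L}_{nll} = -\frac{1}{S}\sum_{ij}
  \ln p_{NB}(Y_{ij};\, l_i\hat{Y}_{ij}, \alpha_j)$.
  The library factor $l_i$ is the spot's total count divided by the median
  over training spots, so sequencing depth is not absorbed into the cell
  scores. $\alpha_j$ is learned jointly with $\theta$, parametrized as
  $\exp(\cdot)$ of a free parameter (initialized at 1) to enforce
  positivity. The mean/inverse-overdispersion parametrization is primary;
  the log-pmf is evaluated in log-gamma form and is tested against
  `dnbinom()` and its Poisson limit.

The output-layer bias is initialized at the inverse softplus of the
per-gene mean target (mean scaled expression for the MSE loss, mean
depth-adjusted count for the NB loss) — a standard mean-matching
initialization. It matters here: IQR-scaled targets can have large
magnitudes, and with a small constant learning rate an uninitialized output
spends the whole training budget reaching the gene means before any
composition signal can be fit.

Training uses AdamW (learning rate $10^{-4}$, batch size 128 bags, weight
decay 0.01 on weight matrices, standard moment defaults), with 20% of spots
held out as a validation set — the split is by spot, so a spot's cells never
straddle the split — and early stopping with patience 20: the returned model
carries the weights of the epoch with the lowest validation loss. The
gradient of the bag mean distributes to instances as $1/k_s$; results are
independent of how bags are packed into batches. All randomness (split,
initialization, epoch shuffles, sampling) derives from one root seed through
named child streams, so a full pipeline repeated with the same seed is
byte-identical.

`max_epochs` defaults to 400 so that patience, not the cap, normally ends
training. The package's own tests run smaller problems (see below) and cap
epochs at 150–400 accordingly; early stopping terminates well before the cap
in every scenario we run.

## Preprocessing and gene selection

* `qc_filter()`: genes need ≥ 200 total counts and detection in ≥ 10% of
  (training) spots; spots need ≥ 1 assigned cell and ≥ 20 counts.
* `select_hvg()`: variance-stabilized standardized variance (loess trend of
  log10 variance on log10 mean, clipped standardized counts), computed per
  slide and aggregated by the number of slides in which a gene ranks in the
  top *n*, then median rank — so slide-specific genes are demoted. With
  very few genes or degenerate mean spread the trend falls back to a flat
  fit.
* `select_svg()` / `morans_i()`: Moran's I on log-normalized values with a
  symmetrized binary 6-nearest-neighbour graph (the hexagonal Visium
  neighbourhood; the index's weights are otherwise unspecified, and we do
  not row-normalize). Because I can be negative, per-slide scores are
  shifted by +1 — an order-preserving positive transform — before the
  geometric mean across slides. Constant genes carry no spatial signal and
  score 0 before the shift.
* `assign_cells_to_spots()`: a cell joins the nearest spot centre within the
  spot radius (boundary inclusive; equidistant ties to the lower spot
  index). The radius is a required input because the pixel size of the
  full-resolution scan varies between slides.
* Quantiles use linear interpolation (R type 7); zero-IQR genes are divided
  by 1.

## The simulation framework

`generate_reference()` draws a clustered synthetic single-cell reference:
per-gene baseline means are log-normal (median 1 transcript/cell, sdlog 1 —
a realistically skewed mean distribution), counts are negative binomial with
size 2 (typical single-cell overdispersion), and each of the K clusters owns
a set of marker genes whose mean is multiplied by `fold_change` in that
cluster only. Highly variable genes are always ranked on the reference, never
on simulated spots, so every scenario shares one gene list.

`run_scenario()` then emulates a slide: latent image cells receive
cluster-informative noisy embeddings (`synthetic_cluster_encode()`: unit
anchors per cluster plus isotropic noise, sd 0.1, d = 16 — cleanly separable,
mirroring embeddings that carry the morphological cluster and nothing more),
k-means (k-means++ seeding, best of 10 restarts) recovers k = 6 morphology
clusters, the 2000 cells nearest each centroid are retained, and a seeded
random bijection matches image clusters to reference clusters. Expression is
assigned per scenario — **random** (any reference row; no
morphology–expression link), **centroid** (the mapped cluster's mean vector;
perfect link), **cell** (a row from the mapped cluster; partial link) — and
spots are synthesized by drawing member cells (each draw becomes a distinct
cell instance, so a bag never repeats an instance and instances never appear
in two bags) and summing their expression exactly. Train and test datasets
use fresh sampling from derived seeds but share the cluster matching. Spot
centres sit on a grid with non-overlapping capture disks and instances are
placed uniformly inside their spot's disk, so geometric linkage reproduces
the bags exactly.

What the simulation does **not** emulate: spatial autocorrelation of cell
types across the slide, segmentation errors, embedding batch effects,
ambient RNA, or spot-boundary cells shared between spots. Passing tests on
these data show that the estimator recovers what the embeddings encode under
the stated coupling — not that any particular tissue reaches a given
correlation.

In the centroid scenario the assigned vectors are cluster means and hence
fractional; the spot "counts" are exact sums but not integers, so the
integer-count validation is relaxed there (and only there).

## Evaluation and downstream scoring

`compute_metrics()` reports per-gene Pearson and Spearman correlations, rMSE
and MAE across spots or cells, with genes of zero variance recorded as
missing and excluded from summary means (an undefined correlation must not
silently become 0), and 95% percentile bootstrap intervals over genes.
`score_cells()` implements marker-gene signature scoring: cells are scaled
to equal total expression, genes standardized, and the score is the mean
over the marker list minus the mean over a control list drawn matched on
expression (25 mean-expression bins, 50 controls per marker's bin, seeded),
with the option of an explicit control list. `rank_genes_by_group()` ranks
genes per group by the Welch t statistic against all remaining cells
(two-sided p on Welch–Satterthwaite df; zero pooled variance guarded at
1e-9); `top_cells()` returns the highest-scoring cells with deterministic
ties; `minmax_per_gene()` maps each gene to [0, 1] for gallery display.

## Problem sizes used by the package's own checks

The bundled tests run the three scenarios at desk scale: reference K = 6,
G = 300, 500 cells/cluster, fold change 5; 2000 spots x 10 cells for the
random and centroid checks (200 reference HVGs) and 1200 spots x 10 cells,
100 HVGs, 3 seeds for the partial-coupling comparison. At these sizes the
random scenario gives mean spot-level PCC within ±0.05 of zero, the centroid
scenario with one-hot encodings reaches mean PCC ≥ 0.9 and matches the
closed-form least-squares composition oracle, and in the cell scenario
marker genes out-correlate the HVG average while the fully supervised
baseline matches or exceeds the weakly supervised model at matched seeds.
The paper-scale regime (5000 spots x 20 cells, 1000 HVGs, external ovarian
reference and self-supervised embeddings) is the function defaults; its
exact published correlations require those external inputs.

## Known limitations

* The scorer sees cells only through their embeddings: signal absent from
  the embedding is unrecoverable regardless of supervision.
* The NB pathway assumes the library factor captures depth; strong
  per-slide composition shifts are not modelled beyond per-slide scaling.
* k-NN Moran weights assume roughly regular spot geometry; highly irregular
  spot layouts may warrant distance-decay weights instead.
* The simulation's morphology clusters are perfectly balanced and noise-free
  relative to real histology.
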