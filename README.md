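# cellmil

Weakly supervised prediction of **single-cell gene expression** from
**spot-level spatial transcriptomics**.

Sequencing-based spatial transcriptomics (10x Visium and kin) measures the
whole transcriptome, but each barcoded capture spot pools the transcripts of
roughly 10–20 cells; the matching H&E image, on the other hand, resolves
individual cells. `cellmil` bridges the two with multiple-instance learning
(MIL): every spot is a *bag*, the cells detected inside it are *instances*,
and the only training label is the bag-level expression vector. A shared
feed-forward scorer f<sub>θ</sub> (three ReLU hidden layers of width 256,
softplus output) maps a cell's image embedding h ∈ R<sup>d</sup> to
non-negative per-gene scores, and the bag prediction is the mean over the
spot's k<sub>s</sub> cells,

&nbsp;&nbsp;&nbsp;&nbsp;ŷ<sub>s</sub> = (1/k<sub>s</sub>) Σ<sub>i=1..k_s</sub> f<sub>θ</sub>(h<sub>i</sub>),

mirroring the physical measurement. Training minimizes either a mean squared
error on library-size log-normalized, robust-scaled spot profiles,
L<sub>mse</sub> = (1/SG) Σ<sub>ij</sub> (Ŷ<sup>p</sup><sub>ij</sub> − Y<sup>p</sup><sub>ij</sub>)²
with y<sup>p</sup><sub>j</sub> = ln(1 + s·y<sub>j</sub>/Σ<sub>j</sub>y<sub>j</sub>), s = 10⁴,
or a negative-binomial likelihood on raw counts,
L<sub>nll</sub> = −(1/S) Σ<sub>ij</sub> ln p<sub>NB</sub>(Y<sub>ij</sub>; l<sub>i</sub>Ŷ<sub>ij</sub>, α<sub>j</sub>),
with spot library factors l<sub>i</sub> and learned gene-wise inverse
overdispersion α<sub>j</sub> (variance μ + μ²/α). AdamW (lr 10⁻⁴, batch 128
bags), a 20% by-spot validation split and early stopping with patience 20
select the returned weights. After training, f<sub>θ</sub> is applied to
individual cells, giving single-cell expression scores from data that never
contained single-cell labels.

The package also ships the surrounding workflow: Space-Ranger-style MTX
readers, gene/spot quality filters, highly and spatially variable gene
selection (batch-aware standardized variance; Moran's I on a 6-nearest-
neighbour graph), geometric cell-to-spot bag construction, a fully synthetic
simulation framework (random / centroid / cell coupling scenarios plus a
clustered single-cell reference generator), evaluation metrics with bootstrap
confidence intervals, marker-gene signature scoring, and a small command-line
interface (`inst/cli/cellmil`). Who it is for: method developers and analysts
who want cell-resolved expression estimates from existing Visium-style data,
or a controlled sandbox to study when weak spot-level supervision suffices.

## Worked example

Simulate a slide in the *cell* scenario (partial coupling between cell
morphology and expression), train the weakly supervised regressor, and
evaluate on an independently simulated test slide:

```r
library(cellmil)

ref <- generate_reference(K = 6, G = 300, cells_per_cluster = 500,
                          fold_change = 5, seed = 1)
cfg <- scenario_config("cell", n_spots = 1200, cells_per_spot = 10, seed = 1)
sim <- run_scenario(cfg, ref)

hvg   <- ref$hvg$gene_id[1:100]
model <- train_mil(sim$train$bags, sim$train$embeddings,
                   sim$train$spot_counts,
                   train_config(seed = 1, max_epochs = 200),
                   loss = "mse", genes = hvg)
glance(model)

pred  <- predict_spots(model, sim$test$bags, sim$test$embeddings)
truth <- lognormalize(sim$test$spot_counts$counts)[, hvg]
report <- compute_metrics(pred, truth, level = "spot")
report
```

```
#> # A tibble: 1 × 8
#>   loss  level n_genes input_dim n_epochs best_epoch best_val_loss encoder
#>   <chr> <chr>   <int>     <int>    <int>      <int>         <dbl> <chr>
#> 1 mse   spot      100        16      108         88         0.596 synthetic_cluster
#> <metrics_report> level = spot, 100 genes
#> # A tibble: 4 × 5
#>   metric  mean ci_low ci_high n_genes_used
#>   <chr>  <dbl>  <dbl>   <dbl>        <int>
#> 1 pcc    0.333  0.279   0.387          100
#> 2 scc    0.332  0.280   0.382          100
#> 3 rmse   1.20   1.18    1.22           100
#> 4 mae    1.10   1.07    1.12           100
```

A mean spot-level Pearson correlation of ~0.33 is the expected regime for
partial morphology–expression coupling at this problem size: expression is
assigned per cell from the matched reference cluster, so only the
cluster-level component is predictable from the embeddings. The designated
marker genes, whose coupling is strongest, sit well above the average
(mean PCC 0.54 here, via
`dplyr::filter(tidy(report), gene_id %in% unlist(ref$marker_sets))`),
while in the `random` scenario the same pipeline yields a mean correlation
of ~0.00 and in the `centroid` scenario (perfect coupling, one-hot
encodings) ~0.92. Per-cell scores come from `predict_cells(model, E)`;
`score_cells()` turns them into marker-signature scores and `top_cells()`
into ranked galleries.

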