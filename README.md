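# cliffgnn

Activity-cliff-aware graph neural networks for single-target
compound–protein affinity prediction, with structured-sparsity
regularization and quantitative atom-attribution evaluation.

## What it does, and for whom

Medicinal chemists optimizing a lead series against one protein target work
with *congeneric* compounds: a shared scaffold, varied decorations, and
occasionally an *activity cliff* — a matched molecular pair whose small
structural difference produces a potency change of a log unit or more.
`cliffgnn` turns those pairs into both a training signal and an
interpretability benchmark:

1. **Pairing.** Compounds (SMILES + pIC50) are matched by a connected
   maximum common substructure (MCS) search; pairs whose shared
   substructure covers at least 50% of both molecules and whose activities
   differ by ≥ 1 log unit become cliff pairs, with binary common/uncommon
   atom masks and MCS-derived ground-truth atom colorings (common 0,
   uncommon atoms of the more potent compound +1, of the less potent -1).
2. **Model.** A message-passing network (edge-conditioned NNConv-style by
   default; GIN and GAT available) embeds 50-d atom / 10-d bond features
   into 32-d node states over 3 layers. Masked readouts pool the common and
   uncommon atoms separately; 32→16 projections feed a final linear
   affinity head, and two parallel subgraph heads decompose each pair's
   predicted activity difference into common and uncommon parts.
3. **Objective.** With pair index k,

   L = L_MSE + L_N + penalty,&emsp;
   L_N = (λ_CN Δŷ_CN + λ_UCN Δŷ_UCN − Δy_k)²,

   where the penalty on the subgraph-head weights β = (β_CN, β_UCN) is the
   group lasso λ(√p_CN‖β_CN‖₂ + √p_UCN‖β_UCN‖₂) or the sparse group lasso
   (1−α)·GL + αλ‖β‖₁.
4. **Attribution.** CAM, Grad-CAM (signed), Gradient × Input and
   integrated gradients produce per-atom scores, evaluated against the
   MCS colorings by global direction (gdir) across MCS thresholds
   0.50–0.95, node-coloring accuracy/F1, Spearman alignment, directional
   AUROC, edge-dropout stability, and paired t / Wilcoxon tests.

Everything is validated on a built-in synthetic congeneric-series
benchmark (8 scaffold series × single-site, single-heavy-atom substituents
with known additive effects + Gaussian noise), whose ground-truth atom
colorings the MCS pipeline provably recovers.

## Worked example

```r
library(cliffgnn)

# synthetic congeneric series: 60 compounds, known additive effects
bench   <- generate_benchmark(synthetic_spec(seed = 17))
dataset <- assemble_pair_dataset(bench$records, min_pairs = 50)
dataset
#> <ac_pair_dataset: 60 compounds, 841 cliff pairs>

# the MCS masks recover the constructed ground truth exactly
validate_against_pipeline(bench$truth, dataset)$agreement
#> [1] 1

# one 70/10/20 split (pairs follow their first ligand), group-lasso training
sp <- make_fold_splits(dataset$compounds, dataset$pairs, k = 1, seed = 1)[[1]]
tr <- train_model(dataset, sp$train_pairs, sp$val_pairs,
                  model_config("edge_conditioned"),
                  loss_config(penalty = "group_lasso"),
                  train_schedule(max_epochs = 90, seed = 11))

pred <- predict_pair_batch(tr$state, dataset, sp$test_pairs)
regression_metrics(pred$yhat, pred$y)
#>      rmse       pcc
#> 0.1478621 0.9942422

# atom attributions on the held-out pairs: does the difference of mean
# uncommon-atom scores point the same way as the activity difference?
cids <- unique(c(dataset$pairs$i[dataset$pairs$pair_id %in% sp$test_pairs],
                 dataset$pairs$j[dataset$pairs$pair_id %in% sp$test_pairs]))
maps <- attribute_all(tr$state, dataset, "gradient_x_input",
                      compound_ids = cids)
gdir_curve(dataset, maps, sp$test_pairs)[["0.50"]]
#> [1] 0.8904762
```

The held-out RMSE (0.148 log units) sits close to the generator's noise
floor (σ = 0.1), the Pearson correlation of 0.99 reflects the 3-log-unit
activity span, and a global direction of 0.89 means the attribution
difference points with the true activity difference for 89% of test
pairs — well above the 0.5 chance level.

A command-line front-end wraps the same pipeline:

```sh
exec/cliffgnn synth    --seed 17 --out runs/demo
exec/cliffgnn train    --seed 17 --out runs/demo --set loss.penalty=group_lasso
exec/cliffgnn evaluate --seed 17 --out runs/demo
```

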