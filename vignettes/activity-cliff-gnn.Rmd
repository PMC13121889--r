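---
title: "Activity-cliff-aware affinity modelling with structured sparsity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity-cliff-aware affinity modelling with structured sparsity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Matched molecular pairs that share a scaffold but differ at a single
substitution site can show potency differences of several log units —
activity cliffs. For a single protein target with limited assay data, these
pairs are the most information-dense observations available: the structural
difference between the two compounds localizes the cause of the activity
difference. `cliffgnn` builds a single-target affinity model around exactly
this signal. Compound pairs are matched by maximum common substructure
(MCS), each molecule is partitioned into common (scaffold) and uncommon
(decoration) atoms, and a message-passing neural network is trained to
predict absolute affinity while a second, node-level objective forces the
*decomposition* of each pair's predicted activity difference into a
common-substructure part and an uncommon-substructure part. Group lasso or
sparse group lasso penalties on the two subgraph prediction heads let the
optimizer suppress whichever branch carries no signal, treating the scaffold
and decoration representations as natural feature groups.

## Data model

A compound is a heavy-atom graph. Each atom carries a 50-dimensional feature
vector (element one-hot over a fixed 35-symbol vocabulary plus an "other"
slot; degree one-hot 0–5; implicit-hydrogen one-hot 0–4; formal charge
clipped to [-1, 1]; aromaticity flag; ring flag) and each bond a
10-dimensional vector (bond-order one-hot single/double/triple/aromatic;
stereo one-hot Z/E/ANY/NONE; conjugation flag; ring flag). The layout is
versioned and queryable via `feature_layout()`, so attribution scores can be
traced back to named descriptors. Every undirected bond is represented as
two directed edges with identical feature rows.

SMILES interpretation is delegated to OpenBabel (through
ChemmineR/ChemmineOB); aromaticity comes from ring perception, ring bonds
are the non-bridge bonds of the heavy-atom graph, and implicit hydrogens are
derived from standard valence rules on the kekulized structure. One known
limitation: the 2-D molblock round trip does not expose double-bond
cis/trans assignments, so the Z/E stereo slots are populated only when the
backend marks a bond "cis or trans" (ANY); otherwise stereo is NONE. The
slots are retained so that stereo-aware feature sets remain layout
compatible.

## Pairing by maximum common substructure

`find_mcs()` searches for the largest *connected* common substructure under
element-exact atom matching and bond-order-exact bond matching, with ring
bonds matching only ring bonds by default. The search is a McGregor-style
branch and bound over candidate atom pairs (implemented in C++), complete
and deterministic: ties on atom count are broken by matched-bond count and
then by canonical (input) atom order, and a per-pair wall-clock budget
(default 10 s) turns pathological pairs into excluded, logged
`mcs_timeout`s rather than hangs. The test suite checks exactness against
an exhaustive subset-enumeration oracle on random graphs small enough to
enumerate.

A pair qualifies as an activity cliff when the shared substructure covers
at least `min_shared_fraction` (default 0.5) of *both* molecules and the
absolute pIC50 difference is at least 1 log unit (inclusive). Pairs are
ordered — the compound earlier in the input table is the pair's first
ligand — and cross-validation assigns each pair to the partition of its
first ligand, which prevents test pairs from anchoring on training
compounds. Ground-truth atom colorings follow the MCS convention: common
atoms 0, uncommon atoms of the higher-activity compound +1, of the
lower-activity compound -1. These labels are an operational proxy, not a
causal claim; distal electronic or conformational effects are invisible to
them.

## Model

Node and edge features are embedded into a shared 32-dimensional space by
separate linear layers. Three message-passing layers follow, each with
additive neighbour aggregation, batch normalization and ReLU. Three
backbones are available:

* `edge_conditioned` (default): an NNConv-style layer whose edge network
  maps each 32-d edge embedding to a full 32 x 32 message weight matrix
  (32 -> 1024 linear map), plus a learned self-transform. Mean readout.
* `gin`: graph isomorphism layer with learnable epsilon; node features
  only. Sum readout.
* `gat`: single-head graph attention with leaky-ReLU scores and self-loops;
  node features only. Mean readout.

The final node embeddings are pooled twice per compound — once under the
common mask, once under the uncommon mask (mean pooling divides by the
number of selected atoms; an empty selection yields the zero vector).
Each pooled vector is projected 32 -> 16; the concatenated 16+16 vector
feeds a final linear affinity head. Two parallel linear subgraph heads
(16 -> 1, weights `beta_cn`, `beta_ucn`) score the projected common and
uncommon representations; their differences across a pair give the
decomposed predicted activity difference. Whether these heads consume the
16-d projections (default) or the raw 32-d readouts is configurable
(`head_input`), since either reading is compatible with the architecture
sketch; the penalized group size `p` follows the choice automatically.
Two further per-node 32 -> 1 linear heads are exposed for inspection
(`node_head_scores()`) but deliberately kept out of the prediction path.

Batch normalization uses batch statistics in training mode and running
statistics (momentum 0.1) in inference mode — the standard contract, stated
explicitly because everything downstream (attribution, evaluation) runs in
inference mode and is therefore deterministic.

The entire forward and backward pass is implemented in vectorized base R
over block-diagonal batch graphs, with hand-derived reverse-mode gradients.
This is not a shortcut: finite-difference agreement of all parameter and
input gradients, across all backbones, poolings and penalty modes, is part
of the test suite (relative tolerance 1e-4).

## Objectives

For a pair k with observed activities $y_i, y_j$ and predictions
$\hat y_i, \hat y_j$, the affinity loss is the per-pair sum of squared
residuals, averaged over the batch. The node-level loss is a single squared
residual per pair,

$$L_N = (\lambda_{CN}\,\Delta\hat y^{CN} + \lambda_{UCN}\,\Delta\hat y^{UCN} - \Delta y)^2,$$

with $\lambda_{CN} = \lambda_{UCN} = 1$ by default. Setting
`mode = "UCN_only"` forces $\lambda_{CN} = 0$, recovering the
uncommon-node-only baseline objective. A two-term alternative (separately
penalizing each branch) is sometimes written in flattened notation; the
single-square reading is implemented because it is the only one in which
the stated exact-decomposition identity ($\Delta\hat y^{CN} +
\Delta\hat y^{UCN} = \Delta y \Rightarrow L_N = 0$) holds.

The structured penalties act on the subgraph head weights only (never the
biases, never the backbone):

* group lasso: $\lambda(\sqrt{p_{CN}}\lVert\beta_{CN}\rVert_2 +
  \sqrt{p_{UCN}}\lVert\beta_{UCN}\rVert_2)$,
* sparse group lasso: $(1-\alpha)$ times the group lasso plus
  $\alpha\lambda\lVert\beta\rVert_1$, so $\alpha = 0$ recovers the group
  lasso and $\alpha = 1$ the lasso.

The $\sqrt{p}$ group-size weighting is the standard convention; a plain-$p$
variant is exposed as `group_weight = "p"` because flattened formula
typography is ambiguous on this point. Penalties enter the objective as
differentiable terms with subgradient 0 at 0 — adequate at these scales;
a proximal update is out of scope. Defaults: $\lambda = 10^{-3}$,
$\alpha = 0.5$, tunable on validation RMSE.

## Training

Adam (initial rate 1e-3) over minibatches of 32 pairs, up to 300 epochs by
default. Validation RMSE drives both a plateau scheduler (halve the rate
after 10 epochs without an improvement greater than 1e-4, floor 1e-5) and
early stopping (30 epochs). The best-validation state is returned, never
the last. One master seed controls initialization and shuffling; per-fold
seeds are derived deterministically, and identical seeds give bit-identical
runs. `cross_validate()` runs k independent seeded 70/10/20 compound-level
splits, re-checks the first-ligand rule each fold, and reports mean, SD and
pair-count-weighted means of RMSE and Pearson correlation.

## Attribution

Four signed per-atom attribution methods target the predicted affinity
(a regression scalar; there are no class logits):

* **CAM** — last-layer node activations dotted with the effective linear
  readout weights (the branch projections composed with the affinity
  head). Only defined for the linear readout path; requesting it under max
  or attention pooling is an error by design.
* **Grad-CAM** — channel weights are the node-mean of
  $\partial\hat y/\partial H^{(L)}$; node scores are the weighted channel
  sums, deliberately *without* the classic ReLU clamp because the ground
  truth labels are signed.
* **Gradient x Input** — input features times prediction gradient, summed
  per atom and per directed edge.
* **Integrated gradients** — trapezoid-rule path integral from the
  all-zero-feature baseline on the same topology (default 64 interpolation
  points, configurable).

Feature-dimension reduction is summation (not mean or L2) so that
closed-form equalities for linear models hold exactly. Edge attributions
are folded onto atoms by averaging the two directed scores of a bond and
splitting the result half to each endpoint; total attribution mass is
conserved. On a genuinely linear model, Gradient x Input and IG coincide
exactly with $w \odot x$; for ReLU models the IG path integrand has kinks,
so completeness against the baseline holds to quadrature accuracy (the
error decreases with the step count; the suite checks both the smooth-model
1e-3 regime and the monotone improvement under step doubling).

Outside a pair context a compound has no masks, so standalone prediction
and attribution use whole-graph masks on both branches; this is the
convention for all evaluation below.

## Evaluation metrics

* **Global direction (gdir)** per pair: 1 when the difference of mean
  uncommon-atom attributions between the two compounds has the sign of the
  true activity difference. An exact tie scores 0 — a zero difference
  cannot preserve the direction of a nonzero cliff. `gdir_curve()` sweeps
  MCS thresholds 0.50–0.95 in 0.05 steps; pair sets are nested by
  construction, and empty subsets report `NA`.
* **Node coloring** accuracy and macro-F1 over uncommon atoms only: a
  signed score is a two-class predictor, and common atoms (label 0) have no
  class under it, so they are excluded; atoms with an exactly zero score
  match neither class and count as errors.
* **Spearman alignment** between scores and the signed labels on uncommon
  atoms (midranked ties), and **directional AUROC**: label +1 atoms scored
  raw, label -1 atoms scored negated, midrank estimator — both
  cross-checked against brute-force implementations in the tests. Note
  that when the comparison universe is exactly the two signed classes (as
  here, uncommon atoms only), the two directional AUROCs coincide
  algebraically; they separate only if a third (neutral) class is added to
  the negatives.
* **Perturbation stability**: Spearman alignment recomputed after dropping
  each bond independently with probability 0, 0.05, 0.10, 0.20, 0.30
  (seeded; rate 0 reproduces the unperturbed value exactly; isolated atoms
  are fine because empty neighbourhoods are legal).
* **Paired tests**: two-sided paired t and Wilcoxon signed-rank p-values
  for fold- or target-paired metric comparisons. Wilcoxon drops zero
  differences (the original procedure) and uses the exact distribution for
  up to 25 untied differences, the normal approximation otherwise.

## The synthetic benchmark

Real kinase benchmarks require an external database download, so validation
rests on a synthetic congeneric series with known ground truth. Eight
amide-type scaffold templates (benzamides, an acetanilide, a pyridine and a
thiophene variant, an ester, an N-methyl amide), each with one substitution
site and a scaffold base activity between 5.0 and 5.55 log units, are
decorated with eight single-heavy-atom substituents (F, Cl, Br, I, C, N, O,
S) whose additive effects span 0–3 log units. Observed pIC50 is the
additive true activity plus Gaussian noise (sd 0.1). The default draw of 60
scaffold-substituent combinations (seed 17) yields several hundred cliff
pairs, mirroring the scale of the smallest single-kinase benchmark sets.

Two generator choices matter. Single-heavy-atom substituents of distinct
elements are *MCS-unambiguous*: no substituent can map into another or into
the scaffold, so the pipeline's masks provably coincide with the
constructed truth (`validate_against_pipeline()` checks this pair by pair).
And multiple scaffold series with different base activities create both
within-series pairs (clean single-site edits) and cross-series pairs,
as real congeneric data would. What the generator does *not* emulate:
multi-atom decorations, correlated or non-additive substituent effects,
stereochemistry, and assay heteroscedasticity. Passing the synthetic
recovery tests therefore demonstrates that the machinery is correct and
that the model can recover an additive structure-activity landscape — not
that it matches any particular experimental benchmark.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full pipeline at desk
scale: the 60-compound default benchmark (several hundred pairs), single
70/10/20 splits, at most 90–120 training epochs with early stopping, and
5 seeds per loss setting for the penalty comparison. These sizes were
chosen so a complete validation runs on one CPU core in minutes while
leaving the reported effects (held-out RMSE near the noise floor, global
direction well above chance) clearly resolved. Other numerics: batch-norm
epsilon 1e-5; Glorot-uniform initialization; improvement threshold 1e-4 on
validation RMSE for both patience rules; max-pooling backward routes
gradients to the first argmax on ties; attention pooling is a
softmax-gated weighted sum with a learned gate vector per branch.

## Command line

The `exec/cliffgnn` script exposes the pipeline as subcommands (`synth`,
`pairs`, `train`, `crossval`, `attribute`, `evaluate`, `report`) driven by
YAML/JSON configs with dotted-path `--set` overrides. Every command writes
a manifest (config hash, seed, package and R versions) next to its
artifacts, and rerunning a command with the same config and seed reproduces
its outputs.

## Known limitations

* Atom matching in the MCS is element-exact; tautomers or charge-shifted
  forms of "the same" scaffold will not merge.
* Z/E stereo featurization is limited by the 2-D backend (slots reserved,
  see above).
* The MCS-derived colorings are a heuristic benchmark; disagreement between
  a model and these labels can reflect genuine long-range chemistry rather
  than attribution error.
* The trained models here are single-target; no pretraining or transfer is
  attempted, and baselines from the wider literature are out of scope.
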