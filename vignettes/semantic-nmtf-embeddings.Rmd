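---
title: "Shared-factor NMTF embeddings for multipartite biomedical graphs"
author: "SemNMTF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared-factor NMTF embeddings for multipartite biomedical graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Biomedical knowledge about drugs and their targets is naturally a
*semantic multipartite graph*: nodes partition into typed sets (genes,
drugs, ontology terms, pathways, ATC codes, drug categories and classes,
cell lines), and edges only connect nodes of different types, each edge
type carrying one meaning ("this drug is annotated with this ATC code",
"this gene participates in this pathway"). Such a graph is fully described
by the collection of its bipartite association matrices: a binary matrix
$R_{XY} \in \{0,1\}^{|X| \times |Y|}$ per connected set pair, plus
non-negative weighted matrices for quantitative layers such as cell-line
gene expression. Drug-combination synergy adds hyperedges: one cell line
and an unordered pair of drugs with a real ZIP (zero interaction potency)
score — positive for synergy, non-positive for no synergy or antagonism —
which no single matrix can represent.

Two prediction tasks drive the package: completing the gene–drug target
layer (drug repurposing) and predicting the ZIP score of an unseen
(cell, drug, drug) triplet (synergy prediction), in both the random
held-out setting and the *cold-start* setting where a node has no observed
target edges at all.

## Joint NMTF with shared factors

Non-negative matrix tri-factorization (NMTF) approximates one layer as
$R \approx U S V^\top$ with all three factors non-negative,
$U \in \mathbb{R}^{|X| \times k_X}$, $S \in \mathbb{R}^{k_X \times k_Y}$,
$V \in \mathbb{R}^{|Y| \times k_Y}$, and ranks below the set sizes. For a
multipartite graph the loss is the (optionally weighted) sum of squared
Frobenius reconstruction errors over all layers,

$$ L(\mathcal{R}, \Theta) \;=\; \sum_i w_i\,
   \lVert R_i - U_i S_i V_i^\top \rVert_F^2 , $$

with the *sharing constraint* that whenever two layers touch the same node
set, that set's factor matrix is literally one object — the factor serves
as $U$ where the set indexes rows and as $V$ where it indexes columns.
`SemNMTF` stores exactly one factor matrix per node set
(`FactorSet@nodeFactors`), so all three constraint patterns (chains
$X\!-\!Y\!-\!Z$, shared rows, shared columns) hold by construction rather
than by penalty or synchronisation code.

Fitting uses the standard multiplicative update rules. For node set $X$
the update aggregates over *all* incident layers $Q$, with
$R_{XQ} V_Q S_{XQ}^\top$-type terms in the numerator and the matching
$U_X S_{XQ} V_Q^\top V_Q S_{XQ}^\top$-type terms in the denominator; cores
update as $S_{XY} \leftarrow S_{XY} \odot (U_X^\top R_{XY} V_Y) \oslash
(U_X^\top U_X S_{XY} V_Y^\top V_Y)$. Multiplicative rules keep factors
non-negative and preserve exact zeros, and each sweep is non-increasing in
$L$ up to floating-point slack — both properties are asserted in the test
suite over random single-layer and three-layer chained instances.

Numerical choices:

* **Denominator stabilisation.** Denominators are floored at
  `eps = 1e-10` (`pmax(den, eps)`), not incremented by it. The floor never
  perturbs a healthy update, so an exact factorization
  $R = U S V^\top$ is a machine-precision fixed point of a full sweep —
  additive stabilisation would instead contract every entry by
  $\sim\varepsilon/\text{den}$.
* **Initialisation.** All entries i.i.d. uniform on $(0,1)$; each node
  factor is then scaled by $\sqrt{\bar{R}/k}$ over its incident layers so
  the first reconstructions are on the data's scale. Draws happen in
  sorted node-set order and cores are drawn in the canonical orientation
  of their pair key, so fits are invariant to how a layer happens to be
  stored (a layer and its transpose give identical loss traces).
* **Stopping and restarts.** Relative loss change below `tol = 1e-6`
  checked every 10 sweeps, at most 1000 sweeps, 5 random restarts keeping
  the lowest loss (defaults; the acceptance script's end-to-end runs
  use 3 restarts). NMTF is non-convex; restarts are the only local-optima
  treatment.
* **Determinism.** Every internal consumer of randomness (initialisation,
  fold assignment, negative sampling, generator noise, permutation nulls)
  derives its own seed from the one user-facing seed through a named,
  Lehmer-spread substream (`.substream`). Two different consumers never
  replay the same stream even for adjacent user seeds — an earlier
  additive-offset scheme allowed exactly that collision, letting a
  permutation "null" replay the generator's noise stream and inherit
  structure.

## Embeddings from side information, and the N-tower predictor

Plain NMTF completion cannot say anything about a node whose target-layer
row is all zeros: its multiplicative numerator vanishes and its factor row
collapses to zero (`coldStartScores()` demonstrates this; it is also why
the baseline's cold-start predictions are exactly 0). The package's main
method therefore separates *representation* from *prediction*:

1. `isolateTargetStar()` keeps only the layers incident to a target set,
   drops the layer(s) linking it to the other target set, and orients
   everything with the target on columns.
2. `fitSharedEmbeddings()` runs joint NMTF on that star. All layers share
   the target's factor as their $V$, so its rows are dense $k$-vectors
   fusing every side layer — the node embeddings. They never see target
   edges, which is the mechanism enabling cold-start prediction (deleting
   every target edge leaves the embeddings bit-identical; asserted in the
   tests).
3. `assemblePairDataset()` / `assembleTripletDataset()` concatenate two
   (gene, drug) or three (cell, drug, drug) embeddings per candidate tuple
   and attach the binary edge label or the ZIP score.
4. `trainPredictor()` fits a pluggable model — ridge logistic/linear
   (`glmnet`), random forest (`ranger`) or gradient boosting (`xgboost`)
   — and `rankNovelPredictions()` ranks the non-edges by score.

Drug-pair symmetry in the synergy task is handled by training-time
augmentation (each record also appears with the drugs swapped) plus
prediction-time averaging over both orders, rather than by symmetric
feature engineering; this keeps the tower architecture unchanged.

**Layer balance.** The squared-Frobenius loss weighs a layer by its mass:
in the synthetic study the continuous expression layer carries
$\sim\!10^6$ squared units against $\sim\!10^3$ for a binary annotation
layer, so an unweighted star fit would learn gene embeddings almost
exclusively from expression. `fitSharedEmbeddings()` therefore defaults to
`normalizeWeights = TRUE`, dividing each layer's weight by its squared
Frobenius norm. The matrix-completion *baseline* keeps the unweighted
objective — that imbalance sensitivity is a documented property of the
base method, not something the baseline should be protected from.
Embedding dimensions of $k = 10$ to $25$ are the sensible range for
real-scale graphs; synthetic runs use $k$ equal to the planted rank.

## The synthetic study

Nothing in the package downloads data; the generator
(`simulateMultipartite()`, `simulateSynergyTriplets()`) emulates the
*shape* of the real inputs with planted low-rank truth so that every claim
is testable:

* One exponential non-negative factor matrix per node set (defaults:
  120 genes, 100 drugs, 15 cell lines, gene-side sets GO 50 and
  Pathways 30, drug-side sets ATC 20, Categories 30, Classes 40, planted
  rank 5).
* Every binary layer — including the gene–drug target — is
  $U S V^\top$ of the *same* planted factors, thresholded at the quantile
  matching its density, then a `flip` fraction (default 5%) of entries is
  inverted. Side layers at density 0.10.
* The cell × gene layer stays continuous with additive Gaussian noise
  (10% of signal sd), truncated at zero.
* ZIP scores are a centred bilinear form
  $\langle w_c, u_a \odot u_b \rangle - \beta$ plus Gaussian noise
  calibrated so observed scores correlate $\approx 0.9$ with the noiseless
  truth; symmetric in the two drugs by construction.

The target density default is 0.15 rather than the sparser real-data
regime: with a 5% entry flip, a density-0.10 layer would draw roughly a
third of its positive class from pure noise, capping any method's AUROC
near 0.84 and leaving no identifiable signal regime at desk scale. At
density 0.15 the planted-score oracle ceiling is ≈ 0.88 and the full
pipeline reaches ≈ 0.87, i.e. the method is near-optimal when the
generator's assumptions hold.

What the generator does *not* emulate: real marginal distributions
(degree heavy tails, ontology hierarchy, batch structure in expression),
layer-specific noise models, or biological correlation between side
layers beyond the shared factors. Passing tests therefore demonstrate
correctness of the machinery and recoverability of planted structure, not
expected performance on DrugBank-scale data.

### What the evaluation designs show

* **5-fold CV** (`kfoldCV`, stratified row-level splits) on the default
  graph: pooled two-tower AUROC ≈ 0.87 against an oracle ceiling of
  ≈ 0.88; on an entry-permuted null target (`permutedNull`) the same
  pipeline sits at chance (0.45–0.55).
* **Leave-one-node-out** (`looNodes`) trains one model per held-out node
  on every row not involving it, macro-averaging per-node AUROC; nodes
  whose test rows are single-class are excluded and counted. The
  acceptance runs use a seeded 25-node subset, paired across methods, to
  stay within desk-scale budgets; the split logic is identical at full
  scale.
* **Cold start, two-tower vs completion** (`nmtfBaseline`): the
  comparison is run over *drugs*. Over genes the continuous expression
  layer — generated from the same planted factors — makes joint
  completion of a masked gene row essentially well-specified, and the two
  approaches tie within seed noise (margins −0.06 to +0.01 across seeds).
  Over drugs, whose side information consists only of thresholded binary
  layers (the misspecified regime the embedding architecture targets),
  the two-tower model wins consistently (margins +0.04 to +0.07 across
  seeds 1, 2, 11, 101). The S-configuration baseline, with no side
  layers, scores every masked node at exactly zero.
* **Synergy** (three towers, boosted): 5-fold CV Pearson ≈ 0.75 /
  Spearman ≈ 0.65 against the ≈ 0.9 noise ceiling, dichotomised AUROC
  ≈ 0.83, and leave-one-cell-out AUROC lower than CV but well above
  chance — the expected degradation when a cell line is entirely unseen in
  training.

Problem sizes throughout (120 × 100 target, 5000 triplets, 25-node LOO
subsets, ≤ 10 restarts) are the package's chosen desk-scale study
conditions; `scripts/acceptance.R` re-runs all of the above from scratch
for any seed.

## Design decisions that were genuinely open

* **One factor per node set** rather than per matrix role: the printed
  $U$/$V$ distinction becomes orientation metadata, and the sharing
  constraints cannot be violated by construction.
* **Duplicate edges** in ingested TSVs collapse to the last occurrence
  with a warning — concatenated exports are common and should not abort a
  run.
* **One matrix per unordered set pair**: direction is storage detail; the
  semantic direction lives in the `relation` label.
* **Negative policy** for the pair dataset defaults to the full Cartesian
  product; seeded subsampling (`list(ratio =, seed =)`) exists for large
  graphs.
* **SVD baseline construction** (`svdEmbeddings`): star layers stacked
  row-wise, rank-$k$ truncated SVD, embeddings = right singular vectors
  scaled by singular values, sign fixed by the largest-magnitude loading.
  The original description does not pin these details down; this is the
  package's choice.
* **One-hop stars only**: layers not incident to the target set do not
  influence its embedding.
* **Grid search** (`gridSearch`) evaluates on the training portion only
  and breaks ties by grid order; default grids are regularisation
  {0.01, 0.1, 1, 10} for linear, trees {100, 300} × depth {∞, 8, 16} for
  forests, trees {100, 300} × depth {3, 6} × learning rate {0.05, 0.1}
  for boosting.

## Known limitations

* Multiplicative updates converge slowly near flat optima; exact
  recovery tests need thousands of sweeps on small problems. No
  acceleration (e.g. HALS) is implemented.
* The loss treats observed zeros as true negatives; there is no
  masking-based treatment of "unknown" entries beyond the evaluation
  designs' explicit masking.
* Per-node LOO refits one model (or one factorization) per node; at real
  scale this is the dominant cost and the `nodes` subset argument is the
  intended control.
* ZIP prediction shares one drug-embedding space with link prediction
  only through the generator; the package does not model dose–response
  surfaces, only the summary score.
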