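# SemNMTF

Semantic multipartite graph embeddings via non-negative matrix
tri-factorization (NMTF), with N-tower predictors for drug–target link
prediction and drug-combination synergy (ZIP score) modelling.

## Who this is for

Computational biologists and cheminformaticians who have heterogeneous
association data — genes annotated to ontology terms and pathways, drugs
annotated with ATC codes, categories and classes, cell lines profiled by
expression, drug pairs scored for synergy — and want to (a) predict new
gene–drug links, including for *cold-start* nodes with no known links,
and (b) predict the synergy score of an unseen (cell line, drug, drug)
triplet. All inputs are plain TSV node/edge/triplet lists; no database
clients or ontology parsers are involved.

## The method

A semantic multipartite graph is the collection of its bipartite
association matrices. Joint NMTF factorizes every layer as
R<sub>XY</sub> ≈ U<sub>X</sub> S<sub>XY</sub> V<sub>Y</sub><sup>⊤</sup>
under the constraint that each node set owns **one** factor matrix shared
across all layers it touches, minimising

&nbsp;&nbsp;&nbsp;&nbsp;L = Σ<sub>i</sub> w<sub>i</sub> ‖R<sub>i</sub> −
U<sub>i</sub> S<sub>i</sub> V<sub>i</sub><sup>⊤</sup>‖²<sub>F</sub>

by multiplicative update rules (non-negativity- and zero-preserving,
monotone in L). Matrix completion U S V<sup>⊤</sup> is the classical
predictor — and fails for nodes with empty rows. The package's main
method instead learns, for each target set, a shared-V NMTF of its
one-hop *star* of side layers (target edges excluded): the rows of the
shared V are dense per-node embeddings. Concatenated embeddings (two
towers for gene–drug pairs, three for cell–drug–drug triplets) feed a
logistic/ridge, random-forest or gradient-boosted predictor. Because the
embeddings never see target edges, cold-start nodes are scored as easily
as any other. A truncated-SVD embedding baseline and the plain NMTF
completion baseline (side-information configurations S/G/D/G+D, 5-fold CV
and leave-one-node-out designs) are included, plus a planted low-rank
synthetic data generator that makes the whole pipeline testable offline.

## Worked example

```r
library(SemNMTF)

spec <- syntheticSpec(seed = 1)          # 120 genes, 100 drugs, 5 side sets,
sim  <- simulateMultipartite(spec)       # 15 cell lines, planted rank 5
sim$graph
#> MultipartiteGraph: 8 node sets, 7 layers
#>   Genes          120 nodes
#>   Drugs          100 nodes
#>   ...
#>   layer Genes~Drugs: 120 x 100, binary

fcfg <- fitConfig(nRestarts = 3, seed = 1, normalizeWeights = TRUE)
embG <- fitSharedEmbeddings(isolateTargetStar(sim$graph, "Genes",
                                              exclude = "Drugs"),
                            "Genes", k = 5, fcfg)
embD <- fitSharedEmbeddings(isolateTargetStar(sim$graph, "Drugs",
                                              exclude = "Genes"),
                            "Drugs", k = 5, fcfg)

ds <- assemblePairDataset(embG, embD, getLayer(sim$graph, "Genes", "Drugs"))
cv <- kfoldCV(ds, predictorSpec("boosted", seed = 1), folds = 5, seed = 1)
metrics(cv)$auroc
#> [1] 0.8670463
```

The pooled cross-validated AUROC of 0.867 sits just under the planted
oracle ceiling (≈ 0.88 under the generator's 5% flip noise): the
embedding pipeline recovers nearly all recoverable signal. On a
permutation-null target (`permutedNull`) the same pipeline scores ≈ 0.5,
and the ten top-ranked novel pairs come from
`rankNovelPredictions(trainPredictor(ds, predictorSpec("boosted")),
embG, embD, getLayer(sim$graph, "Genes", "Drugs"), topN = 10)`.

A command-line wrapper over the same functions ships at
`inst/cli/semnmtf` (subcommands `simulate`, `factorize`, `embed`,
`train`, `predict`, `evaluate`; YAML config, JSON manifest per run).

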