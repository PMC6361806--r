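# driverCNN

Cancer driver genes — genes whose somatic mutations confer a selective
growth advantage on tumor cells — are vastly outnumbered by passengers,
and the few labeled positives per cancer type make their prediction a
small-sample, imbalanced classification problem. **driverCNN** addresses
it for computational cancer-genomics practitioners working from standard
cohort data: a MAF-style somatic mutation table, an FPKM expression
matrix, and a driver gene list.

## Method

For every gene the package computes twelve mutation-derived features:
the fractions of silent, nonsense, splice-site, missense,
recurrent-missense, frameshift-indel, inframe-indel, and lost-start/stop
mutations; pseudocounted missense:silent and non-silent:silent ratios;
and two normalized Shannon entropies

E_i = −Σ_j p_j log2(p_j) / log2(m),  p_j = κ_j / m,

measuring the positional clustering of missense mutations over codons
and of all mutations over consequence bins (hotspot-driven oncogenes
score low, uniformly mutated passengers high).

Expression (FPKM → TPM → filtered log2-TPM) yields a k-nearest-neighbor
gene similarity network under Pearson correlation r(g_i, g_j). Each gene
g_i is presented to a small 1-D convolutional network as the 2k × 12
matrix

φ_i = [x_i, x_s1, x_i, x_s2, …, x_i, x_sk],

interleaving its feature vector with its k ranked neighbors. With filter
size and stride 2, each first-layer window pairs the gene with one
similar gene; the stack (2 CONV–ReLU–max-pool blocks of 24 filters, one
48-node FC layer, sigmoid head; rows 14 → 7 → 3 → 2 → 1 at k = 7) outputs
a driver probability. Class imbalance is handled by drawing five
balanced driver/passenger sets, evaluating each by repeated 10-fold
cross-validation with pooled held-out ROC curves (AUC via Eq.-4-style
FPR/TPR sweep), and ranking unlabeled genes by their probability
averaged over the five per-set models (bagging). A seeded synthetic
cohort generator (planted hotspot mutations, block-correlated
expression) makes the whole pipeline testable without downloads.

The vignette (`vignettes/driver-gene-cnn.Rmd`) documents the model,
every tunable parameter, and the design choices in detail.

## Worked example

```r
library(driverCNN)

cohort <- simulateCohort(simulationConfig(seed = 1))   # 300 genes, 30 drivers
prep   <- prepareCohort(cohort$records, cohort$expression,
                        cohort$drivers, k = 7)
cv     <- evaluateCohort(prep, nSets = 5, folds = 10, repeats = 1, seed = 2)
cv$meanAuc
#> [1] 0.994
cv$perRun
#>   set rep       auc
#> 1   1   1 0.9900000
#> 2   2   1 0.9933333
#> 3   3   1 0.9866667
#> 4   4   1 1.0000000
#> 5   5   1 1.0000000
```

Each row is one cross-validation run on one balanced set: all 30
planted drivers against 30 sampled unknowns, split into 10 folds, with
the held-out probabilities pooled into a single ROC curve. A mean AUC of
0.994 says the network recovers the planted driver signal (missense
hotspots, skewed mutation-class composition, driver-enriched
co-expression neighborhoods) almost perfectly; on label-permuted data
the same protocol returns AUC ≈ 0.5. To rank new candidates:

```r
rk <- rankCohort(prep, nSets = 5, seed = 3)
head(rk$ranking)        # rank, gene, mean probability across 5 models
```

A command-line front end wrapping the same functions ships in
`inst/scripts/driver-cnn.R` (subcommands `features`, `preprocess-expr`,
`network`, `simulate`, `evaluate`, `rank`, `gridsearch`,
`learning-curve`), e.g.

```sh
Rscript inst/scripts/driver-cnn.R simulate --seed 1 --out fixtures/
Rscript inst/scripts/driver-cnn.R evaluate --maf fixtures/mutations.maf.tsv \
    --expr fixtures/expression.fpkm.tsv --drivers fixtures/drivers.txt \
    --k 7 --seed 1 --out results/
```

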