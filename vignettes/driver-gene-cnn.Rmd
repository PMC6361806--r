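---
title: "Predicting cancer driver genes from mutation features and co-expression neighborhoods"
author: "driverCNN maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cancer driver genes from mutation features and co-expression neighborhoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driverCNN)
```

## The problem

Driver genes carry somatic mutations that confer a selective growth
advantage on tumor cells; passengers mutate without oncogenic effect.
Separating the two from cohort-scale mutation catalogs is hard because the
labeled positives are few (tens per cancer type), the negatives are not
truly labeled (any "unknown" gene may be an undiscovered driver), and the
informative signal is spread across several weak per-gene statistics.

driverCNN classifies genes by combining two kinds of evidence:

1. **Mutation-derived features** — twelve per-gene statistics summarizing
   the composition and positional clustering of a gene's somatic
   mutations.
2. **Co-expression similarity** — a k-nearest-neighbor (kNN) network over
   genes built from Pearson correlation (PCC) of tumor expression
   profiles; similar genes tend to have related roles, so a gene's
   neighborhood carries information its own features may lack.

Rather than concatenating the two, each gene $g_i$ is presented to a
small one-dimensional convolutional network (CNN) as a $2k \times n_f$
matrix $\phi_i$ that interleaves its feature vector with those of its $k$
most-correlated neighbors. The first convolution layer, with filter size
and stride 2, then sees exactly one (gene, neighbor) pair per window, so
its filters learn how a candidate driver's statistics compare with those
of its most similar genes.

## The twelve mutation features

For every gene with at least one variant after quality control, the
package computes (in this fixed order): the fractions of silent,
nonsense, splice-site, missense, recurrent-missense, frameshift-indel,
inframe-indel, and lost-start/stop mutations; the missense-to-silent and
non-silent-to-silent ratios; and two normalized Shannon entropies,

$$E_i = \frac{-\sum_j p_j \log_2 p_j}{\log_2 m}, \qquad p_j = \kappa_j/m,$$

where for the *missense position entropy* $m$ is the gene's missense
count and $\kappa_j$ the missense hits in codon $j$, and for the *total
mutation entropy* $m$ counts all mutations and the bins are: one bin per
missense codon, one bin per distinct silent change, one pooled bin for
the inactivating classes (nonsense, lost start/stop, splice site), and
one bin per remaining class. Hotspot-driven oncogenes score low
entropies; uniformly peppered passengers score high. Note the
normalization is by $\log_2 m$, not by the bin count, so $E_i = 1$
exactly when every mutation is unique ($m$ singleton bins).

Choices the feature definitions leave open, and how this package
resolves them:

* **$m \le 1$.** The normalizer $\log_2 m$ vanishes; the entropy is
  defined as 0, since a single mutation carries no positional
  information.
* **Ratio features with zero silent counts.** Both ratios use add-one
  pseudocounts, $(x+1)/(s+1)$, keeping them finite and
  order-preserving.
* **Recurrence.** A missense mutation is *recurrent* when its codon
  carries at least two missense hits across the cohort's samples —
  recurrence is judged within the cohort, not against an external
  catalog.
* **Silent-mutation identity.** Distinct silent changes get their own
  entropy bins, keyed by codon when available, else by the raw
  protein-change string, else one bin per record. Missense records
  without a codon likewise fall back to per-record bins.
* **Unrecognized variant classes** map to an `other` class that counts
  toward totals (and one entropy bin) but toward no named fraction, and
  is excluded from the non-silent count, since its coding consequence is
  unknown.

Quality control precedes extraction: samples with more than 1000
intragenic variants (hypermutated tumors, threshold strict `>`) are
removed entirely, since their mutations are dominated by global
mutagenic processes rather than selection.

## Expression preprocessing and the kNN network

FPKM matrices are converted to TPM by per-sample rescaling to a column
sum of $10^6$; TPM values below 1 are treated as unreliable and zeroed;
$\log_2(\mathrm{TPM}+1)$ is applied; genes expressed in fewer than 10% of
tumor samples are dropped. The gene universe is then the intersection of
genes with mutation features and surviving expression.

The network connects every gene to the $k$ genes with the largest PCC
to it, computed on the log2-TPM values (preprocessing precedes network
construction in the workflow; correlations on the log scale are far less
dominated by a handful of highly expressed genes). The defaults follow
the published grid search over this model family: $k = 7$ is the
recommended neighborhood size for cohorts without their own search.
Numerical corner cases:

* **Ties** at the k-th correlation are broken by ascending gene symbol,
  making the network invariant to row order.
* **Zero-variance profiles** have undefined PCC (0/0); they are assigned
  correlation 0 against everything, with a warning, so callers can drop
  them — they carry no similarity information.
* The network is stored **directed**: each gene owns its ranked list,
  which is exactly what tensorization consumes. (A mutual/undirected
  reading would leave genes with fewer than $k$ ranked neighbors and has
  no consumer in this pipeline.)

## The input tensor and its layout

$\phi_i$ interleaves the center gene with its ranked neighbors:
$[x_i, x_{s_1}, x_i, x_{s_2}, \dots, x_i, x_{s_k}]$. The published
description fixes only the $2k \times n_f$ shape from $k+1$ distinct
vectors; interleaving is this package's choice because, with filter =
stride = 2, it makes first-layer window $j$ cover exactly the pair
$(x_i, x_{s_j})$ — each filter becomes a learned comparison between a
gene and one similar gene, which matches the stated intent of letting
similar genes share filters. The layout is isolated in `buildTensor()`,
so alternatives (e.g. $k$ center copies followed by $k$ neighbors) are a
local change.

Features are standardized per column (z-scores) before tensorization.
The scaler is fit on **training genes only** and applied to held-out
genes, so no statistic of a test gene leaks into training; zero-spread
features get scale 1 and standardize to 0.

## The classifier

The architecture is `ncl` CONV–ReLU–POOL blocks, flatten, `nfl`
fully-connected ReLU layers, and a single sigmoid output; defaults
`ncl = 2, nfl = 1, ncn = 24, nfn = 48` with filter, pooling window and
both strides equal to 2, no padding on the first CONV and zero padding
(bottom row) on later CONVs. Pooling is max-pooling with floor boundary:
an incomplete trailing window is dropped. At $k = 7$ the row counts
propagate $14 \to 7 \to 3 \to 2 \to 1$. Configurations whose stack
collapses to zero rows (e.g. `ncl = 2` at $k = 3$) are rejected at build
time, and the grid search records them as infeasible rather than
failing.

Because stride equals filter size, convolution windows never overlap and
each CONV layer is a reshape of row pairs followed by one dense matrix
multiplication. The package exploits this: forward pass, exact
backpropagation, and an Adam optimizer are implemented directly on that
structure in a few hundred lines of matrix code. The net has only a few
thousand parameters, and training a fold takes well under a second, so a
heavyweight framework is unnecessary. Gradients are verified against
central-difference numerical differentiation in the test suite.

Training details (the published description is silent on optimization;
these are package choices, all configurable via `trainConfig()`):
binary cross-entropy loss with a sigmoid head; Adam at learning rate
$10^{-3}$; batch size 16; at most 300 epochs; early stopping on a 10%
validation split with patience 25, restoring the best weights. The
pooling operator (max) is likewise a package default. All randomness —
initialization, shuffling, validation split — is derived from explicit
seeds, so identical seeds give identical weights.

## Evaluation protocol

Driver labels are few and negatives unlabeled, so evaluation uses
**downsampling with bagging**: `nSets = 5` balanced sets are drawn, each
pairing all drivers with an equal-size uniform sample of unknown genes.
Each set is evaluated by 10-fold cross-validation — plain random
splits, with a bounded re-shuffle if a training partition ends up
single-class — and each run's held-out scores are pooled into **one**
ROC curve (fold-wise curve averaging is the one-line alternative, kept
out of the default because pooling uses every gene exactly once at its
natural weight). The CV is repeated 5 times per set; the headline number
is the mean AUC over the $5 \times 5 = 25$ runs, with per-run values
reported.

The ROC sweep treats each distinct score as a threshold, so ties produce
diagonal segments; the trapezoidal AUC then equals the Mann–Whitney
statistic $P(s^+ > s^-) + \tfrac12 P(s^+ = s^-)$, which the tests verify
by brute-force pair counting. For *de novo* prediction, one model per
balanced set is trained on all of that set's genes and every unknown
gene is ranked by its probability averaged across the five models.

## The synthetic cohort generator

Real cohorts require controlled-access downloads, so the package ships a
seeded generator that emulates the structure the method assumes — it is
first-class, tested code, not a test fixture. Defaults (fixed once,
as the package's study conditions): 300 genes, 30 drivers, 60 tumor
samples.

* **Mutations.** Passenger genes draw Poisson(8) mutations from a
  background class mix (50% missense, 30% silent, the rest split among
  nonsense, splice-site, indels, lost start/stop, and a 3% `other`
  share) with uniform codon positions over a 500-codon gene. Drivers
  draw Poisson(20) missense mutations, 80% of which land on one
  gene-specific hotspot codon, plus background non-missense mutations at
  the passenger rate's non-missense share — so drivers show elevated
  missense fractions, skewed non-silent:silent ratios, and low
  positional entropy, the same contrasts the features were designed to
  capture. Hypermutated samples (>1000 variants) can be injected to
  exercise QC. Mutation counts are Poisson because the generator needs
  only a minimal dispersion model; that choice is confined to this
  module.
* **Expression.** Genes are partitioned into 10 blocks sharing a
  per-sample latent factor; log2 expression is baseline + factor +
  Gaussian noise (sd 0.5), exponentiated to FPKM-like values. Drivers
  are packed into 3 blocks, so driver neighborhoods are enriched for
  drivers — the property the network-structured convolution exploits.

What the generator does **not** emulate: trinucleotide mutational
signatures, realistic gene lengths and background mutation-rate
covariates, subclonal structure, expression outliers, and batch effects.
Passing tests on synthetic cohorts therefore demonstrate that the
implementation recovers the signal it models, not that the method
attains any particular accuracy on real tumor data.

## Problem sizes and verification

The test suite and the acceptance script run the full protocol on the
default 300-gene cohort with 5 balanced sets and 10-fold CV (one repeat
for the end-to-end checks; the 5×5 bookkeeping is verified with a
reduced epoch budget), sizes chosen so a complete run takes a couple of
minutes on one CPU. On that cohort the pipeline reaches mean AUC ≈ 0.99,
label-permuted controls sit near 0.5, and drivers hidden from training
rank above passengers — numbers recomputed, not stored, on every run of
`scripts/acceptance.R`.

## Known limitations

* The CNN implementation fixes filter/pool/stride at 2 (the published
  geometry); other geometries would need overlapping-window convolution.
* Gene identifiers are matched as strings; no HGNC symbol
  standardization service is consulted.
* Unknown genes are treated as passengers during training; bagging over
  five negative draws mitigates but cannot eliminate label noise from
  undiscovered drivers.
* The comparison baselines of the original study (random forests on the
  same features, SVMs, positional-clustering callers) are out of scope.

## A worked example

```{r example, eval = FALSE}
library(driverCNN)

cohort <- simulateCohort(simulationConfig(seed = 1))
prep <- prepareCohort(cohort$records, cohort$expression,
                      cohort$drivers, k = 7)
cv <- evaluateCohort(prep, nSets = 5, folds = 10, repeats = 1, seed = 2)
cv$meanAuc
cv$perRun
```

See the README for the printed output of this example and for the
command-line front end (`inst/scripts/driver-cnn.R`).
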