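---
title: "Multitask convolutional HLA imputation: models, metrics and fine-mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitask convolutional HLA imputation: models, metrics and fine-mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Classical HLA alleles are expensive to type directly, so large association
studies infer them statistically from the SNV haplotypes flanking the MHC
region, using a reference panel in which both SNVs and HLA alleles were typed
and phased. The MHC's LD structure is strong but irregular: some alleles are
tagged by nearby SNVs whose correlation decays smoothly with distance, while
others are identified only by combinations of markers spread across the
region. Methods built on local LD lose accuracy exactly there, and
low-frequency alleles — where reference information is thinnest — suffer most.
This package implements an imputation model that reads an entire megabase-
scale window at once: a multitask convolutional network trained on phased
haplotypes, together with the dosage-based accuracy metrics, uncertainty and
LD diagnostics, and the downstream case-control fine-mapping pipeline that a
study using such a model needs.

## The model

Each training example is one haplotype. The SNVs inside a gene group's window
are one-hot encoded (a 2 x W binary array: reference/alternative channel per
position). A shared stack of two 1-d convolutions (each followed by batch
normalization, ReLU, dropout and max-pooling) and one fully-connected layer
feeds gene-specific softmax heads, one per HLA gene of the group, each of
which outputs a probability vector over that gene's alleles. The per-gene
probability of an allele on a haplotype is its haploid dosage; summing an
individual's two haplotypes gives the familiar diploid dosage in [0, 2], and
per-gene dosages sum to 2 by construction.

Genes are trained jointly in groups reflecting the MHC's block structure
(`default_groups()` carries the four standard gene sets restricted to what a
panel actually types). The per-gene cross-entropy losses are balanced each
optimization step by min-norm task weighting (`mgda_ub_weights()`): the
gradient of each task's loss is taken with respect to the shared
representation output, and Frank–Wolfe iteration finds the simplex weights
minimizing the norm of the combined gradient, so no gene's loss dominates the
shared layers. Optimization is Adam; 5% of *samples* (not haplotypes — an
individual's two haplotypes never straddle the split) are held out as a
sub-validation set, and the parameter snapshot with the best sub-validation
loss within the patience window is kept.

Allele nomenclature is hierarchical (2-digit allele group, 4-digit protein,
6-digit synonymous). `hla_cnn_hierarchy()` trains the coarsest resolution
first and initializes each finer model's shared layers from the coarser one
(hierarchical fine-tuning); genes untyped at a finer resolution reuse their
coarser labels so all genes of a group stay at an equivalent level.

### Default hyperparameters

`model_hyperparams()` defaults to 128/64 convolution filters with kernels
7/5, pool width 2, a 256-unit shared layer, dropout 0.25, batch size 64,
learning rate 1e-3, at most 200 epochs with patience 20, and a 5%
sub-validation fraction. These are sensible CPU-scale settings, not tuned
optima; every analysis in this package passes its own configuration, and the
examples below state the sizes they use. Two settings deserve comment:

* *Missing target variants.* Model-window SNVs absent from a target are
  filled with the reference one-hot and logged (an `error` mode is
  available); imputation refuses to run when less than half the window is
  present.
* *Sub-validation granularity.* The early-stopping split is drawn at the
  sample level to avoid leakage between a person's two haplotypes.

## Uncertainty and diagnostics

*MC dropout.* `mc_dropout_sample()` keeps dropout active at prediction time
and performs T (default 200) stochastic passes; each pass yields a best-guess
diploid genotype per gene. With t the number of passes agreeing with the
deterministic best guess, the uncertainty of that genotype is the binary
entropy H = −(t/T log(t/T) + (1−t/T) log(1−t/T)) in natural log units
(`mc_entropy()`), zero iff t ∈ {0, T} and maximal (ln 2) at t = T/2.
`uncertainty_roc()` scores how well H ranks incorrectly imputed genotypes
(midrank ROC-AUC, the Mann–Whitney statistic), against the dosage-based
comparator score `dosage_discrimination_score()` — the negative posterior
probability of the best-guess genotype. The comparator's exact form is not
canonical; the product of the two haplotype argmax probabilities is used here
and documented as a choice.

*LD-decay AUC.* `ld_profile()` computes r² between an allele indicator and
every SNV across panel haplotypes; `auc_ld_decay()` ranks SNVs by distance
from the gene's representative coordinate, normalizes the cumulative-r² curve
to the unit square (rank-based x axis, robust to irregular marker spacing)
and integrates by the trapezoid rule through the origin. A flat r² profile is
a straight diagonal and integrates to exactly 0.5; distance-concentrated LD
makes the curve convex upward (all mass on the nearest SNV gives 1 − 1/(2W)).
`max_ld_within()` reports the strongest single tag among the k nearest SNVs
(default 100), and `accuracy_vs_ld_regression()` regresses allele-level
accuracy on the AUC adjusted for allele frequency — a method that exploits
region-wide information shows a weaker dependence than one reading only
local LD.

*Sensitivity maps.* `smoothgrad()` adds Gaussian noise (SD 0.1 on the
continuously relaxed one-hot scale; n = 200 draws) to carrier haplotypes,
averages absolute input gradients of the allele's loss, and sums the two
one-hot channels per position.

## Accuracy metrics

Writing A1, A2 for an individual's true alleles at a locus and D for imputed
dosage, locus-level dosage sensitivity is Se(L) = Σᵢ (Dᵢ(A1) + Dᵢ(A2)) / 2n,
with predicted haplotypes assigned to truth slots to maximize the credited
dosage and per-individual credit capped at 2 (relevant only to external
dosage files; softmax dosages cannot exceed it). Se(A) decomposes this per
allele over its m true carrier haplotypes; PPV(A) divides the same credited
mass by the total imputed mass of A, penalizing false-positive mass;
r²(A) is the squared Pearson correlation between imputed and true diploid
dosages; and the concordance rate CR repeats Se with hard best-guess calls,
so CR = Se whenever probabilities are 0/1. Se(L) equals the frequency-
weighted mean of Se(A) by construction. Aggregation over frequency bins
(defaults 0.5%, 1%, 2%, 5%, 10%, 50%) weights Se/PPV/CR by allele frequency;
r² is averaged on the signed correlation after Fisher z-transformation and
squared after back-transformation, with undefined entries (constant dosage
vectors) excluded and counted rather than imputed as zero.

`cross_validate()` runs sample-level k-fold (default 10) rounds, drawing the
early-stopping split inside each training fold so held-out data never
influences stopping, pools held-out probabilities across folds, and scores
them against the panel truth with frequencies computed on the full panel.

## The synthetic panel generator

Real reference panels are access-restricted, so `simulate_reference_panel()`
builds panels with the statistical features the method consumes: one binary
SNV "backbone" per classical allele (haplotype clusters), a tagging-fidelity
parameter φ (probability a haplotype derives from its own allele's backbone),
a recombination-style donor-switch rate ρ along the map, independent per-SNV
noise ε, Dirichlet or explicit allele-frequency spectra (rare alleles down to
0.5%), pairwise 2-digit parents over the 4-digit alleles, an amino-acid
dictionary guaranteed to separate every allele pair (with one fully
multiallelic position), and an optional second population with logit-normal
frequency perturbation and population-private alleles. A tag-placement knob
(`near`/`far`/`uniform`) controls whether allele-distinguishing SNVs sit next
to the gene or at the window edges, which is what the LD-decay diagnostics
exercise. Defaults — φ = 0.95, ε = 0.02, ρ = 0.01, Dirichlet concentration
0.8, divergence 0.5 — were fixed once as plausible desk-scale analogues of a
well-genotyped panel.

What the generator does *not* emulate: coalescent genealogies, mutation-rate
calibration, marker ascertainment, phasing error (targets are taken as
correctly pre-phased), or the real MHC's position-dependent LD texture. In
particular, haplotypes are literally mosaics of allele backbones, so a
1-nearest-haplotype classifier is close to the Bayes decoder on these panels
— a property real panels do not share. Tests passing on synthetic panels
demonstrate the machinery is correct and directionally faithful, not that
real-data accuracies are reproduced.

`simulate_cohort()` draws haplotype pairs from a panel and assigns case
status from a logistic model with additive dosage effects of designated
causal residues or alleles, filling requested case/control quotas by
rejection; two-population mode samples population-specific pools.

## Fine-mapping

After imputation, markers with cross-validated r² below 0.7 are removed
(boundary kept: `filter_by_cv_r2()`). Association uses additive logistic
regression of dosages on case status (`logistic_fit()`, IRLS, aliased
columns dropped and logged, separation flagged and excluded from selection);
multiallelic amino-acid positions are tested by likelihood-ratio omnibus
tests on the k−1 non-reference residue columns (`omnibus_test()`, reference =
most frequent residue, chi-square with k−1 df; LRT chosen as the standard
convention for multiallelic HLA tests). `stepwise_conditional()` scans all
markers each round, adds the top signal's conditioning set while it passes
5×10⁻⁸, and stops otherwise; conditioning is gene-level (all 4-digit alleles
minus a reference) outside a designated tight-LD region and variant-level
inside it (default region: the DRB1–DQA1–DQB1 block, where gene-level
conditioning would blind neighbouring genes). `transethnic_merge()` unions
HLA markers across cohorts (dosage 0 where absent), intersects SNVs and
removes palindromic A/T–C/G pairs, zero-fills each cohort's PCs off-block and
appends population indicators. `variance_explained()` maps the observed-scale
R² of the fitted HLA linear predictor to the liability scale with the
standard threshold-model transformation with ascertainment correction,
R²_liab = R²_obs · K²(1−K)² / (z² P(1−P)) — a documented implementation
choice validated against a direct liability simulation in the test suite.

## Numerical and design notes

* Exact probability ties in best-guess calls break to the lexicographically
  first allele name and are reported.
* Fisher z-transformation clamps |r| at 1 − 1e-12 before atanh.
* All randomness (simulation, splits, initialization, shuffling, dropout,
  noise) derives from named substreams of one master seed; repeated runs are
  bit-identical.
* The min-norm solver stops on a Frank–Wolfe duality gap below 1e-6
  (relative), or 2000 iterations.
* Multiallelic SNVs are rejected at parse time; the model consumes biallelic
  markers only. Missing genotypes are rejected: panels are distributed
  complete and phased, and targets must be pre-phased/imputed upstream.
* Where a panel types an allele only at a coarse resolution, the coarse label
  stands in at finer resolutions, mirroring common panel practice.

## Problem sizes used in the packaged analyses

The test suite and the acceptance script run entirely on synthetic panels
sized for a single desktop CPU: 200–400 haplotypes and 40–60 SNVs per group
for recoverability and uncertainty analyses, 1,600 haplotypes for the
rare-allele comparison, and compact networks (16/8 filters, 32–64 shared
units) trained for tens to a few hundred epochs. These sizes were chosen as
the package's own benchmarking conditions; the model itself has no intrinsic
scale limits beyond memory.

## Known limitations

* Pure-R training is practical to a few thousand haplotypes and a few
  hundred window SNVs; industrial-scale panels would want a compiled
  backend.
* Early stopping on sub-validation cross-entropy favours calibration of
  common alleles; very rare alleles (a handful of carriers) remain hard, and
  on backbone-mosaic synthetic panels the 1-nearest-haplotype baseline is
  near-optimal by construction, so the network's rare-allele advantage seen
  on real panels does not always transfer to this simulator.
* The uncertainty index is per-gene, not per-allele; it flags doubtful
  genotypes, not doubtful dosage mass.
* No unphased-genotype mode, no liftover, and no strand auto-correction
  beyond palindromic-SNV removal during cohort merging.
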