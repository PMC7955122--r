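# hlaimpute

Imputation of classical HLA alleles and amino-acid polymorphisms from phased
SNV haplotypes with a multitask convolutional neural network, plus the
evaluation metrics, uncertainty and linkage-disequilibrium diagnostics, and
trans-ethnic MHC fine-mapping machinery that a study built on such imputation
needs.

## Who this is for

Statistical geneticists working in the MHC region: large GWAS cohorts carry
SNV genotypes but not HLA types, so classical alleles (2-/4-/6-digit) and the
amino-acid residues they encode are inferred from flanking haplotypes using a
typed, phased reference panel, then tested for disease association. The MHC's
LD is strong but irregular, and low-frequency alleles are hard; this package
implements a window-wide convolutional model rather than a local-LD one,
and everything needed to quantify when and why it works.

## The model

For a group of neighbouring HLA genes, each haplotype's SNVs inside the
group's window (default 500 kb per side) are one-hot encoded and passed
through a shared stack — conv → batch-norm → ReLU → dropout → max-pool,
twice, then a fully-connected layer — feeding one softmax head per gene.
The head for gene *g* outputs P(allele | haplotype), a haploid dosage;
an individual's diploid dosage of allele A is the sum over the two
haplotypes, so per-gene dosages sum to 2. Training minimizes per-gene
categorical cross-entropy with Adam, balancing the genes' losses each step by
min-norm task weighting (MGDA-UB, solved by Frank–Wolfe on the task-gradient
Gram matrix), early-stops on a 5% sample-level sub-validation split, and
transfers shared-layer parameters from coarser to finer allele resolutions
(hierarchical fine-tuning). Prediction-time dropout (MC dropout, T = 200
passes) yields a per-genotype uncertainty: the binary entropy
H = −(t/T·log(t/T) + (1−t/T)·log(1−t/T)) of the agreement count t with the
deterministic best guess.

Accuracy follows the dosage cross-tabulation conventions: per-locus
sensitivity Se(L) = Σᵢ(Dᵢ(A1ᵢ) + Dᵢ(A2ᵢ))/2n under the truth-optimal
haplotype arrangement; its per-allele decomposition Se(A); PPV(A) = credited
mass / total imputed mass; dosage r²; and the best-guess concordance rate CR.
Aggregates are frequency-weighted, with Fisher z-transformation for r².
Fine-mapping filters markers at cross-validated r² ≥ 0.7, tests biallelic
markers by logistic Wald tests and multiallelic amino-acid positions by
likelihood-ratio omnibus tests (reference = most frequent residue,
df = k−1), runs forward stepwise conditioning at P < 5×10⁻⁸ with gene-level
conditioning sets (variant-level inside the tight-LD DRB1–DQA1–DQB1 block),
merges cohorts trans-ethnically (union of HLA markers, palindromic SNVs
removed, PCs zero-filled off-block, population indicators), and converts the
fitted effects to liability-scale variance explained via the threshold model
with ascertainment correction.

Real reference panels are access-restricted, so the package ships a synthetic
phased-panel simulator (allele-backbone haplotype clusters, tunable tagging
fidelity, recombination mosaic, skewed frequency spectra with rare alleles,
two-population mode, amino-acid dictionary, case-control cohort generator on
the logistic scale) that every analysis and test runs on.

## Worked example

```r
library(hlaimpute)

## a phased reference panel: 200 samples, 2 genes, 4 alleles each
sim <- simulate_reference_panel(sim_config(
  n_haplotypes = 400, n_snvs_per_group = 60, seed = 7))

hp <- model_hyperparams(conv1_filters = 16, conv2_filters = 8,
                        kernel1 = 5, kernel2 = 3, shared_fc_units = 32,
                        batch_size = 32, max_epochs = 30, patience = 6,
                        seed = 3)
model <- hla_cnn(sim$panel, sim$groups[[1]], resolution = 4, hp = hp)
model
#> Multitask convolutional HLA imputation model
#> Group: grp1 ( G1, G2 ) at 4 digit
#> Window: 60 SNVs; heads: 4/4 alleles
#> Stopped at epoch 27 (best sub-validation loss 0.2839 at epoch 21 )

## impute a masked copy of the panel and score against the truth
probs <- predict(model, mask_hla(sim$panel))
rep <- accuracy_report(probs, list(G1 = truth_genotypes(sim$panel, "G1"),
                                   G2 = truth_genotypes(sim$panel, "G2")))
rep$loci
#>   gene   n        Se    CR
#> 1   G1 200 0.8620234 0.940
#> 2   G2 200 0.7905074 0.915
```

`Se` is the imputed dosage mass credited to the true alleles (1 = perfect
soft calls); `CR` the fraction of best-guess alleles matching the truth under
the optimal diploid arrangement — this deliberately brief 30-epoch fit calls
92–94% of alleles correctly, with dosage mass diffused because the generator
keeps 5% of haplotypes on foreign backbones and flips 2% of SNVs (longer
training sharpens both; in the noiseless limit 10-fold cross-validation
reaches CR ≈ 0.99). Proper benchmarking uses
`cross_validate(panel, groups, k = 10, ...)`, which never scores a sample
predicted by a model that saw it.

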