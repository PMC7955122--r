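Package: hlaimpute
Title: Multitask Convolutional Imputation of HLA Alleles and MHC Fine-Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputation of classical HLA alleles and amino-acid polymorphisms
    from phased SNV haplotypes with a multitask convolutional neural network
    trained on typed reference panels. Provides readers and writers for
    SNP2HLA/Beagle-style phased panels and phased VCF, a synthetic phased-panel
    and case-control cohort simulator, dosage-based accuracy metrics
    (sensitivity, PPV, r-squared, concordance) with frequency-binned
    aggregation and a cross-validation harness, Monte Carlo dropout
    uncertainty, linkage-disequilibrium decay diagnostics and input
    sensitivity maps, and trans-ethnic stepwise conditional association
    analysis with liability-scale variance explained.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, pracma, optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
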