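
test_that("diploid dosages add the two haplotype probabilities", {
  p <- matrix(c(1, 0, 0,
                0, 1, 0), 2, byrow = TRUE,
              dimnames = list(NULL, c("a1", "a2", "a3")))
  pr <- allele_probs(list(G1 = p))
  d <- diploid_dosage(pr)
  expect_equal(unname(d$dosages[1, ]), c(1, 1, 0))
  p2 <- matrix(0.5, 2, 2, dimnames = list(NULL, c("a1", "a2")))
  expect_equal(unname(diploid_dosage(allele_probs(list(G1 = p2)))$dosages[1, ]),
               c(1, 1))
  pr3 <- random_probs(20, 4)
  expect_true(all(abs(rowSums(diploid_dosage(pr3)$dosages) - 2) < 1e-4))
})

test_that("residue dosages are linear in classical dosages and conserve mass", {
  dict <- aa_dictionary(data.frame(
    gene = "G1", allele = c("01:01", "02:01"), position = 9,
    residue = c("S", "Y")))
  mk <- function(d1, d2) dosage_table(
    matrix(c(d1, d2), 1, dimnames = list("i1", NULL)),
    data.frame(id = c("G1*01:01", "G1*02:01"), gene = "G1",
               class = "classical_allele", allele = c("01:01", "02:01"),
               position = NA, residue = NA))
  aa <- derive_aa_dosages(mk(2, 0), dict)
  expect_equal(unname(aa$dosages[1, "G1_pos9_S"]), 2)
  aa2 <- derive_aa_dosages(mk(1.2, 0.8), dict)
  expect_equal(unname(aa2$dosages[1, ]), c(1.2, 0.8))
  expect_equal(sum(aa2$dosages), 2)
  # uncovered allele mass is flagged, not silently dropped
  dict_partial <- aa_dictionary(data.frame(
    gene = "G1", allele = "01:01", position = 9, residue = "S"))
  aa3 <- derive_aa_dosages(mk(1.2, 0.8), dict_partial)
  expect_equal(unname(attr(aa3, "uncovered")[1, "G1:pos9"]), 0.8)
})

test_that("best guess takes the argmax with lexicographic tie-break", {
  p <- matrix(c(0.7, 0.2, 0.1,
                0.5, 0.5, 0.0), 2, byrow = TRUE,
              dimnames = list(NULL, c("a1", "a2", "a3")))
  expect_message(bg <- best_guess(allele_probs(list(G1 = p))), "ties")
  expect_equal(unname(bg$G1[1, ]), c("a1", "a1"))
})

test_that("optimal pairing maximizes matches over slot assignments", {
  expect_equal(optimal_pairing(c("a", "b"), c("b", "a")), 2L)
  expect_equal(optimal_pairing(c("a", "a"), c("a", "b")), 1L)
  expect_true(is.na(optimal_pairing(c("a", "b"), c("unknown", "a"))))
  # exhaustive check against a permutation oracle over a 3-allele set
  alls <- c("x", "y", "z")
  for (g1 in alls) for (g2 in alls) for (t1 in alls) for (t2 in alls) {
    brute <- max(sum(c(g1, g2) == c(t1, t2)), sum(c(g2, g1) == c(t1, t2)))
    expect_equal(optimal_pairing(c(g1, g2), c(t1, t2)), brute)
  }
})

test_that("locus sensitivity follows the dosage-credit definition", {
  # truth (a,a) and (a,b); hard per-haplotype calls
  p <- matrix(c(1, 0,
                1, 0,
                1, 0,
                0, 1), 4, byrow = TRUE, dimnames = list(NULL, c("a", "b")))
  truth <- rbind(c("a", "a"), c("a", "b"))
  pr <- allele_probs(list(G = p))
  expect_equal(sensitivity_locus(pr, truth, "G"), 1.0)
  rep <- accuracy_report(pr, list(G = truth))
  expect_equal(rep$loci$CR, 1.0)
})

test_that("metrics equal the brute-force cross-tabulation oracle", {
  for (case in 1:50) {
    pr <- random_probs(20, 4, seed = case)
    truth <- random_truth(20, 4, seed = 100 + case)
    rep <- accuracy_report(pr, list(G1 = truth))
    orc <- oracle_metrics(unclass(pr)$G1, truth)
    tb <- rep$alleles[match(orc$alleles$allele, rep$alleles$allele), ]
    expect_equal(tb$Se, orc$alleles$Se, tolerance = 1e-10)
    expect_equal(tb$PPV, orc$alleles$PPV, tolerance = 1e-10)
    expect_equal(tb$CR, orc$alleles$CR, tolerance = 1e-10)
    expect_equal(tb$r2, orc$alleles$r2, tolerance = 1e-10)
    expect_equal(rep$loci$Se, orc$SeL, tolerance = 1e-10)
    # locus Se decomposes as the frequency-weighted mean of allele Se
    w <- tb$m / sum(tb$m)
    expect_equal(rep$loci$Se, sum(w * tb$Se), tolerance = 1e-10)
  }
})

test_that("concordance equals sensitivity under hard calls", {
  for (case in 1:10) {
    set.seed(case)
    k <- 3L; n <- 15L
    hard <- diag(k)[sample.int(k, 2 * n, replace = TRUE), ]
    colnames(hard) <- sprintf("a%d", 1:k)
    pr <- allele_probs(list(G1 = hard))
    truth <- random_truth(n, k, seed = 50 + case)
    rep <- accuracy_report(pr, list(G1 = truth))
    expect_equal(rep$loci$Se, rep$loci$CR, tolerance = 1e-12)
    ok <- rep$alleles$m > 0
    expect_equal(rep$alleles$Se[ok], rep$alleles$CR[ok], tolerance = 1e-12)
  }
})

test_that("metrics are invariant to allele order and sample permutation", {
  pr <- random_probs(15, 4, seed = 3)
  truth <- random_truth(15, 4, seed = 4)
  rep1 <- accuracy_report(pr, list(G1 = truth))
  # permute allele columns
  p <- unclass(pr)$G1[, c(3, 1, 4, 2)]
  rep2 <- accuracy_report(allele_probs(list(G1 = p)), list(G1 = truth))
  expect_equal(rep1$alleles, rep2$alleles)
  # permute samples
  set.seed(9); perm <- sample(15)
  hap_perm <- as.vector(rbind(2 * perm - 1, 2 * perm))
  rep3 <- accuracy_report(
    allele_probs(list(G1 = unclass(pr)$G1[hap_perm, ])),
    list(G1 = truth[perm, , drop = FALSE]))
  expect_equal(rep1$alleles, rep3$alleles)
  expect_equal(rep1$loci$Se, rep3$loci$Se)
})

test_that("individuals with unknown truth are excluded from the locus", {
  pr <- random_probs(10, 3, seed = 5)
  truth <- random_truth(10, 3, seed = 6)
  truth[4, ] <- c("unknown", "unknown")
  rep <- accuracy_report(pr, list(G1 = truth))
  expect_equal(rep$loci$n, 9L)
})

test_that("aggregation weights by frequency and Fisher-z transforms r", {
  rep <- structure(list(alleles = data.frame(
    gene = "G", allele = c("a", "b"), freq = c(0.9, 0.1), m = c(9L, 1L),
    n = 10L, Se = c(1, 0), PPV = c(1, 0), r = c(0.6, 0.8),
    r2 = c(0.36, 0.64), CR = c(1, 0))), class = "accuracy_report")
  agg <- aggregate_metrics(rep, freq_bins = 1)
  expect_equal(agg$Se[agg$bin == "all"], 0.9)
  # closed-form Fisher-z aggregate at equal weight
  rep$alleles$freq <- c(0.5, 0.5)
  agg2 <- aggregate_metrics(rep, freq_bins = 1)
  expect_equal(agg2$r2[agg2$bin == "all"],
               tanh((atanh(0.6) + atanh(0.8)) / 2)^2, tolerance = 1e-12)
  # identical r2 values aggregate to themselves
  rep$alleles$r <- c(0.7, 0.7); rep$alleles$r2 <- 0.49
  agg3 <- aggregate_metrics(rep, freq_bins = 1)
  expect_equal(agg3$r2[agg3$bin == "all"], 0.49, tolerance = 1e-12)
})

test_that("r2 matches the standard correlation formula", {
  pr <- random_probs(20, 3, seed = 11)
  truth <- random_truth(20, 3, seed = 12)
  rep <- accuracy_report(pr, list(G1 = truth))
  p <- unclass(pr)$G1
  for (a in colnames(p)) {
    dimp <- p[seq(1, 39, 2), a] + p[seq(2, 40, 2), a]
    dtru <- (truth[, 1] == a) + (truth[, 2] == a)
    mx <- mean(dimp); my <- mean(dtru)
    r_manual <- sum((dimp - mx) * (dtru - my)) /
      sqrt(sum((dimp - mx)^2) * sum((dtru - my)^2))
    expect_equal(rep$alleles$r2[rep$alleles$allele == a], r_manual^2,
                 tolerance = 1e-10)
  }
})

test_that("the 1-NN baseline handles exact matches and ties", {
  v <- data.frame(id = c("v1", "v2"), chrom = "6", pos_bp = c(10L, 20L),
                  ref_allele = "A", alt_allele = "G")
  H <- matrix(c(0L, 0L,
                1L, 1L,
                0L, 1L), 3, 2, byrow = TRUE)
  # train: 4 haplotypes (2 samples)
  Htr <- rbind(H[1, ], H[2, ], H[1, ], H[2, ])
  train <- phased_panel(v, Htr, c("s1", "s2"),
                        list(G = list(`4` = c("01:01", "02:01",
                                              "01:01", "02:01"))),
                        gene_pos = c(G = 15))
  gr <- gene_group("g", "G", c(G = 15), 10L)
  # exact match
  tg <- matrix(rep(H[1, ], 2), 2, byrow = TRUE,
               dimnames = list(NULL, c("v1", "v2")))
  pr <- baseline_knn_impute(train, tg, gr)
  expect_equal(unname(pr$G[1, "01:01"]), 1)
  # equidistant target splits probability
  tg2 <- matrix(rep(H[3, ], 2), 2, byrow = TRUE,
                dimnames = list(NULL, c("v1", "v2")))
  pr2 <- baseline_knn_impute(train, tg2, gr)
  expect_equal(unname(pr2$G[1, ]), c(0.5, 0.5))
  # noiseless panel: left-out half imputed with full concordance
  sim <- noiseless_sim(160L)
  tr <- panel_subset(sim$panel, 1:60)
  te <- panel_subset(sim$panel, 61:80)
  prb <- baseline_knn_impute(tr, mask_hla(te), sim$groups[[1]])
  repb <- accuracy_report(prb, list(G1 = truth_genotypes(te, "G1"),
                                    G2 = truth_genotypes(te, "G2")))
  expect_gte(mean(repb$loci$CR), 0.97)
})

test_that("cross-validation partitions samples and is seed-deterministic", {
  sim <- noiseless_sim(20L)
  cv1 <- cross_validate(sim$panel, sim$groups, k = 2, method = "knn",
                        seed = 4)
  cv2 <- cross_validate(sim$panel, sim$groups, k = 2, method = "knn",
                        seed = 4)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(sort(unique(cv1$folds)), 1:2)
  # every haplotype received a prediction exactly once (rows sum to 1)
  expect_true(all(abs(rowSums(unclass(cv1$probs)$G1) - 1) < 1e-9))
})
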