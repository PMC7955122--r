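# Shared fixtures, built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# small hyperparameter set so unit tests train in seconds
test_hp <- function(...) {
  args <- list(conv1_filters = 16L, conv2_filters = 8L, kernel1 = 5L,
               kernel2 = 3L, pool = 2L, shared_fc_units = 32L,
               dropout_rate = 0.25, batch_size = 32L,
               learning_rate = 1e-3, max_epochs = 30L, patience = 6L,
               seed = 3L)
  override <- list(...)
  args[names(override)] <- override
  do.call(model_hyperparams, args)
}

# a perfectly decodable two-gene panel (phi = 1, no noise, no recombination)
noiseless_sim <- function(n_haplotypes = 200L, seed = 7L) {
  simulate_reference_panel(sim_config(
    n_haplotypes = n_haplotypes, n_snvs_per_group = 40L,
    tagging_fidelity = 1, snv_noise_rate = 0, recomb_switch_rate = 0,
    seed = seed))
}

# random valid allele-probability object: n individuals, one gene,
# k alleles named a1..ak (sorted)
random_probs <- function(n, k, gene = "G1", seed = 1L) {
  set.seed(seed)
  p <- matrix(rgamma(2 * n * k, 1), 2 * n, k)
  p <- p / rowSums(p)
  colnames(p) <- sprintf("a%d", seq_len(k))
  allele_probs(stats::setNames(list(p), gene))
}

# random truth genotypes over the same allele names
random_truth <- function(n, k, seed = 2L) {
  set.seed(seed)
  matrix(sprintf("a%d", sample.int(k, 2 * n, replace = TRUE)), n, 2)
}

# write a toy beagle file: 2 samples, 3 SNVs, one HLA gene with 2 alleles.
# hla_rows: named list allele digits -> P/A vector (4 haplotypes)
write_toy_beagle <- function(dir, hla_rows = list(
  `01` = c("P", "A", "P", "A"), `02` = c("A", "P", "A", "P"))) {
  bgl <- file.path(dir, "toy.bgl")
  mk <- file.path(dir, "toy.markers")
  lines <- c("I id s1 s1 s2 s2",
             "M rs1 A G A A",
             "M rs2 C C C T",
             "M rs3 T T A A")
  for (d in names(hla_rows))
    lines <- c(lines, paste(c("M", paste0("HLA_A_", d), hla_rows[[d]]),
                            collapse = " "))
  writeLines(lines, bgl)
  mkl <- c("rs1\t100\tA\tG", "rs2\t200\tC\tT", "rs3\t300\tT\tA")
  for (d in names(hla_rows))
    mkl <- c(mkl, paste0("HLA_A_", d, "\t250\tP\tA"))
  writeLines(mkl, mk)
  bgl
}

# ---- independent brute-force cross-tabulation oracle -----------------------
# For each individual both assignments of predicted haplotypes to truth slots
# are enumerated explicitly; metrics are then plain sums over the table.
oracle_metrics <- function(p, truth) {
  n <- nrow(truth)
  alleles <- colnames(p)
  getp <- function(h, a) { j <- match(a, alleles); if (is.na(j)) 0 else p[h, j] }
  slot_hap <- matrix(0L, n, 2L)
  for (i in seq_len(n)) {
    h <- c(2L * i - 1L, 2L * i)
    if (getp(h[1], truth[i, 1]) + getp(h[2], truth[i, 2]) >=
        getp(h[1], truth[i, 2]) + getp(h[2], truth[i, 1]))
      slot_hap[i, ] <- h else slot_hap[i, ] <- rev(h)
  }
  calls <- alleles[apply(p, 1, which.max)]
  out <- NULL
  for (a in unique(as.vector(truth))) {
    num <- 0; m <- 0L; cr <- 0L
    for (i in seq_len(n)) for (k in 1:2) if (truth[i, k] == a) {
      m <- m + 1L
      num <- num + getp(slot_hap[i, k], a)
      cr <- cr + as.integer(calls[slot_hap[i, k]] == a)
    }
    total <- sum(vapply(seq_len(2 * n), function(h) getp(h, a), 0))
    j <- match(a, alleles)
    dimp <- if (is.na(j)) rep(0, n) else
      p[seq(1, 2 * n, 2), j] + p[seq(2, 2 * n, 2), j]
    dtru <- (truth[, 1] == a) + (truth[, 2] == a)
    r2 <- if (sd(dimp) > 0 && sd(dtru) > 0) cor(dimp, dtru)^2 else NA_real_
    out <- rbind(out, data.frame(allele = a, m = m, Se = num / m,
                                 PPV = if (total > 0) num / total else NA,
                                 CR = cr / m, r2 = r2))
  }
  credit <- vapply(seq_len(n), function(i)
    min(2, getp(slot_hap[i, 1], truth[i, 1]) +
          getp(slot_hap[i, 2], truth[i, 2])), 0)
  list(alleles = out[order(out$allele), ], SeL = sum(credit) / (2 * n))
}

# brute-force simplex grid search over task weights (independent oracle)
grid_min_norm <- function(G, step = 0.01) {
  M <- tcrossprod(G)
  ws <- seq(0, 1, step)
  best <- Inf
  if (nrow(G) == 2L) {
    for (w1 in ws) {
      w <- c(w1, 1 - w1)
      best <- min(best, drop(t(w) %*% M %*% w))
    }
  } else {
    for (w1 in ws) for (w2 in seq(0, 1 - w1, step)) {
      w <- c(w1, w2, 1 - w1 - w2)
      best <- min(best, drop(t(w) %*% M %*% w))
    }
  }
  best
}
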