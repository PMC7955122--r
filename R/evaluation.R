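#' Construct an allele-probability object
#'
#' Per-haplotype, per-gene probability vectors over that gene's alleles; rows
#' are haplotypes (two adjacent per individual), columns alleles. Column names
#' are sorted lexicographically; each row must sum to 1 within 1e-5.
#'
#' @param probs named list of haplotype-by-allele matrices, one per gene.
#' @param sample_ids individual ids (half the row count).
#' @export
allele_probs <- function(probs, sample_ids = NULL) {
  for (g in names(probs)) {
    p <- probs[[g]]
    if (is.null(colnames(p))) stop("probability columns must be named")
    probs[[g]] <- p[, order(colnames(p)), drop = FALSE]
    if (any(abs(rowSums(p) - 1) > 1e-5))
      stop("probabilities for ", g, " do not sum to 1")
  }
  n_hap <- nrow(probs[[1]])
  if (is.null(sample_ids)) sample_ids <- paste0("I", seq_len(n_hap %/% 2L))
  structure(probs, class = "allele_probs", sample_ids = sample_ids)
}

#' Diploid classical-allele dosages from haplotype probabilities
#'
#' The dosage of allele A in individual i is the sum of A's probability on the
#' individual's two haplotypes, so dosages per gene sum to 2 by construction.
#'
#' @param probs an \code{allele_probs} object.
#' @return A \code{\link{dosage_table}} of class \code{classical_allele}.
#' @export
diploid_dosage <- function(probs) {
  n_hap <- nrow(probs[[1]])
  if (n_hap %% 2L != 0L) stop("odd haplotype count; need two per individual")
  ids <- attr(probs, "sample_ids")
  D <- NULL; info <- NULL
  for (g in names(probs)) {
    p <- unclass(probs)[[g]]
    d <- p[seq(1L, n_hap, 2L), , drop = FALSE] +
      p[seq(2L, n_hap, 2L), , drop = FALSE]
    D <- cbind(D, d)
    info <- rbind(info, data.frame(
      id = paste0(g, "*", colnames(p)), gene = g, class = "classical_allele",
      allele = colnames(p), position = NA_integer_, residue = NA_character_,
      stringsAsFactors = FALSE))
  }
  rownames(D) <- ids
  dosage_table(D, info)
}

#' Amino-acid dosages from 4-digit classical dosages
#'
#' The dosage of a residue at a position is the sum of the dosages of the
#' 4-digit alleles carrying that residue, keeping residue dosages consistent
#' with the classical dosages (a fully covered position sums to 2 per
#' individual). Alleles absent from the dictionary contribute to a flagged
#' per-position \code{"uncovered"} mass.
#'
#' @param classical \code{\link{dosage_table}} of 4-digit classical alleles.
#' @param dict an \code{aa_dictionary}.
#' @return A \code{\link{dosage_table}} of residue columns
#'   (class \code{residue_binary}), with attributes \code{positions} (the
#'   multiallelic position layout) and \code{uncovered} (individuals x
#'   gene:position uncovered mass, when nonzero).
#' @export
derive_aa_dosages <- function(classical, dict) {
  e <- dict$entries
  cls <- classical$info$class == "classical_allele"
  D <- NULL; info <- NULL; unc <- NULL; unc_names <- character(0)
  positions <- NULL
  for (g in unique(classical$info$gene[cls])) {
    gi <- which(cls & classical$info$gene == g)
    alleles <- classical$info$allele[gi]
    eg <- e[e$gene == g, , drop = FALSE]
    if (!nrow(eg)) next
    for (pos in sort(unique(eg$position))) {
      ep <- eg[eg$position == pos, , drop = FALSE]
      covered <- alleles %in% ep$allele
      if (!any(covered)) { warning("position ", pos, " of ", g,
                                   " covers no panel allele; skipped"); next }
      resid <- sort(unique(ep$residue[ep$allele %in% alleles]))
      for (r in resid) {
        carry <- gi[alleles %in% ep$allele[ep$residue == r]]
        D <- cbind(D, rowSums(classical$dosages[, carry, drop = FALSE]))
        info <- rbind(info, data.frame(
          id = paste0(g, "_pos", pos, "_", r), gene = g,
          class = "residue_binary", allele = NA_character_,
          position = pos, residue = r, stringsAsFactors = FALSE))
      }
      positions <- rbind(positions, data.frame(
        gene = g, position = pos, n_residues = length(resid),
        stringsAsFactors = FALSE))
      if (any(!covered)) {
        unc <- cbind(unc, rowSums(classical$dosages[, gi[!covered],
                                                    drop = FALSE]))
        unc_names <- c(unc_names, paste0(g, ":pos", pos))
      }
    }
  }
  rownames(D) <- rownames(classical$dosages)
  out <- dosage_table(D, info)
  attr(out, "positions") <- positions
  if (!is.null(unc)) {
    colnames(unc) <- unc_names
    attr(out, "uncovered") <- unc
  }
  out
}

#' Best-guess genotypes
#'
#' Per haplotype, the highest-probability allele; exact ties are broken by
#' lexicographic allele name (and reported via a message).
#'
#' @param probs an \code{allele_probs} object.
#' @return Named list per gene: individuals x 2 character matrix of alleles
#'   (unordered pair, stored sorted).
#' @export
best_guess <- function(probs) {
  out <- list()
  for (g in names(probs)) {
    p <- unclass(probs)[[g]]
    ties <- sum(apply(p, 1L, function(r) sum(r == max(r)) > 1L))
    if (ties > 0L)
      message(g, ": ", ties,
              " exact probability ties broken lexicographically")
    a <- colnames(p)[max.col(p, ties.method = "first")]
    g1 <- a[c(TRUE, FALSE)]; g2 <- a[c(FALSE, TRUE)]
    out[[g]] <- cbind(pmin(g1, g2), pmax(g1, g2))
  }
  out
}

#' Truth genotypes of a panel gene
#'
#' @param panel labeled \code{\link{phased_panel}}.
#' @param gene gene name.
#' @param resolution 2, 4 or 6.
#' @return individuals x 2 character matrix (may contain \code{"unknown"}).
#' @export
truth_genotypes <- function(panel, gene, resolution = 4L) {
  v <- panel$hla_labels[[gene]][[as.character(resolution)]]
  if (is.null(v)) stop("gene ", gene, " untyped at ", resolution, "-digit")
  cbind(v[c(TRUE, FALSE)], v[c(FALSE, TRUE)])
}

#' Optimal pairing of guessed and truth genotypes
#'
#' Number of matches (0, 1 or 2) between an unordered guessed allele pair and
#' the truth pair, maximized over the two assignments of guesses to truth
#' slots.
#'
#' @param guess,truth length-2 character vectors.
#' @return Integer in 0:2, or NA if the truth contains \code{"unknown"}.
#' @export
optimal_pairing <- function(guess, truth) {
  if (any(truth == "unknown")) return(NA_integer_)
  max((guess[1] == truth[1]) + (guess[2] == truth[2]),
      (guess[1] == truth[2]) + (guess[2] == truth[1]))
}

# per-individual slot attribution under the dosage-optimal arrangement:
# assign the two predicted haplotypes to the two truth slots so that the
# dosage credited to the truth alleles is maximal. Returns, per individual,
# the probability row index assigned to each truth slot.
slot_assignment <- function(p, truth) {
  n <- nrow(truth)
  assign <- matrix(0L, n, 2L)
  pcol <- function(h, a) { j <- match(a, colnames(p))
    if (is.na(j)) 0 else p[h, j] }
  for (i in seq_len(n)) {
    h1 <- 2L * i - 1L; h2 <- 2L * i
    straight <- pcol(h1, truth[i, 1]) + pcol(h2, truth[i, 2])
    crossed <- pcol(h1, truth[i, 2]) + pcol(h2, truth[i, 1])
    assign[i, ] <- if (crossed > straight) c(h2, h1) else c(h1, h2)
  }
  assign
}

# core per-gene accuracy computation; returns allele table + locus summary
gene_accuracy <- function(p, truth, freq = NULL) {
  known <- truth[, 1] != "unknown" & truth[, 2] != "unknown"
  truth <- truth[known, , drop = FALSE]
  hap_keep <- rep(known, each = 2L)
  p <- p[hap_keep, , drop = FALSE]
  n <- nrow(truth)
  if (!n) stop("no individuals with truth genotypes at this locus")
  assign <- slot_assignment(p, truth)
  alleles <- colnames(p)
  slots_truth <- as.vector(t(truth))                 # 2n truth alleles
  slots_hap <- as.vector(t(assign))                  # assigned hap row
  slot_p <- function(a) { j <- match(a, alleles)
    v <- numeric(length(slots_hap))
    if (!is.na(j)) v <- p[slots_hap, j]
    v }
  # hard best-guess call per assigned haplotype
  calls <- alleles[max.col(p, ties.method = "first")]
  all_alleles <- sort(unique(c(alleles, slots_truth)))
  tab <- data.frame(allele = all_alleles, freq = NA_real_, m = NA_integer_,
                    n = n, Se = NA_real_, PPV = NA_real_, r = NA_real_,
                    r2 = NA_real_, CR = NA_real_, stringsAsFactors = FALSE)
  for (ai in seq_along(all_alleles)) {
    a <- all_alleles[ai]
    carrier <- slots_truth == a
    m <- sum(carrier)
    tab$m[ai] <- m
    fq <- m / (2 * n)
    if (!is.null(freq)) {
      v <- suppressWarnings(as.numeric(freq[a]))
      if (length(v) == 1L && !is.na(v)) fq <- v
    }
    tab$freq[ai] <- fq
    pa <- slot_p(a)
    total_mass <- sum(pa)
    if (m > 0) {
      tab$Se[ai] <- sum(pa[carrier]) / m
      tab$CR[ai] <- mean(calls[slots_hap][carrier] == a)
    }
    if (total_mass > 0 && m > 0)
      tab$PPV[ai] <- sum(pa[carrier]) / total_mass
    # r2 on diploid dosages vs truth counts
    j <- match(a, alleles)
    if (!is.na(j)) {
      dimp <- p[seq(1, 2 * n, 2), j] + p[seq(2, 2 * n, 2), j]
      dtru <- (truth[, 1] == a) + (truth[, 2] == a)
      if (stats::sd(dimp) > 0 && stats::sd(dtru) > 0) {
        tab$r[ai] <- stats::cor(dimp, dtru)
        tab$r2[ai] <- tab$r[ai]^2
      }
    }
  }
  # locus-level: dosage credit (capped at 2 per individual) and concordance
  credit <- pmin(slot_p_sum_by_ind(p, truth, assign), 2)
  matches <- vapply(seq_len(n), function(i)
    optimal_pairing(sort(calls[assign[i, ]]), truth[i, ]), 0L)
  list(alleles = tab,
       locus = data.frame(n = n, Se = sum(credit) / (2 * n),
                          CR = sum(matches) / (2 * n)))
}

slot_p_sum_by_ind <- function(p, truth, assign) {
  vapply(seq_len(nrow(truth)), function(i) {
    s <- 0
    for (k in 1:2) {
      j <- match(truth[i, k], colnames(p))
      if (!is.na(j)) s <- s + p[assign[i, k], j]
    }
    s
  }, 0)
}

#' Imputation accuracy report
#'
#' Computes, per allele, the truth frequency, dosage sensitivity Se(A)
#' (imputed dosage credited to true carrier haplotypes under the optimal
#' diploid arrangement, over the carrier count), positive predictive value
#' PPV(A) (credited dosage over total imputed mass), squared Pearson
#' correlation r2(A) between imputed and true diploid dosages, and the
#' best-guess concordance rate CR(A); and per locus the dosage sensitivity
#' Se(L) and concordance CR(L). Individuals with unknown truth at a locus are
#' excluded from that locus.
#'
#' @param probs an \code{allele_probs} object.
#' @param truth named list per gene of individuals x 2 truth allele matrices
#'   (see \code{\link{truth_genotypes}}).
#' @param freq optional named list per gene of reference allele frequencies
#'   (e.g. computed on the full panel in cross-validation).
#' @return Object of class \code{accuracy_report} with data.frames
#'   \code{alleles} and \code{loci}.
#' @export
accuracy_report <- function(probs, truth, freq = NULL) {
  alleles <- NULL; loci <- NULL
  for (g in names(probs)) {
    if (is.null(truth[[g]])) next
    res <- gene_accuracy(unclass(probs)[[g]], truth[[g]], freq[[g]])
    alleles <- rbind(alleles, cbind(gene = g, res$alleles))
    loci <- rbind(loci, cbind(gene = g, res$locus))
  }
  structure(list(alleles = alleles, loci = loci), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, digits = 3, ...) {
  cat("Per-locus accuracy:\n")
  print(format(x$loci, digits = digits), row.names = FALSE)
  cat("\nPer-allele accuracy:\n")
  print(format(x$alleles, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Single-metric accuracy accessors
#'
#' Thin wrappers over \code{\link{accuracy_report}} returning one quantity:
#' locus dosage sensitivity Se(L), allele dosage sensitivity Se(A), allele
#' positive predictive value PPV(A), allele dosage r2, or the best-guess
#' concordance rate (locus or allele level).
#'
#' @param probs an \code{allele_probs} object covering \code{gene}.
#' @param truth individuals x 2 truth matrix for that gene.
#' @param gene gene name.
#' @param allele allele name (for allele-level metrics).
#' @export
sensitivity_locus <- function(probs, truth, gene) {
  accuracy_report(probs, stats::setNames(list(truth), gene))$loci$Se
}

#' @rdname sensitivity_locus
#' @export
sensitivity_allele <- function(probs, truth, gene, allele) {
  tb <- accuracy_report(probs, stats::setNames(list(truth), gene))$alleles
  v <- tb$Se[tb$allele == allele]
  if (!length(v) || is.na(v)) stop("Se undefined: no true carriers of ",
                                   allele)
  v
}

#' @rdname sensitivity_locus
#' @export
ppv_allele <- function(probs, truth, gene, allele) {
  tb <- accuracy_report(probs, stats::setNames(list(truth), gene))$alleles
  v <- tb$PPV[tb$allele == allele]
  if (!length(v) || is.na(v)) stop("PPV undefined for ", allele,
                                   " (no imputed mass or no carriers)")
  v
}

#' @rdname sensitivity_locus
#' @export
r2_allele <- function(probs, truth, gene, allele) {
  tb <- accuracy_report(probs, stats::setNames(list(truth), gene))$alleles
  tb$r2[tb$allele == allele]     # NA when a dosage vector is constant
}

#' @rdname sensitivity_locus
#' @param level \code{"locus"} or \code{"allele"}.
#' @export
concordance <- function(probs, truth, gene, allele = NULL,
                        level = c("locus", "allele")) {
  level <- match.arg(level)
  rep <- accuracy_report(probs, stats::setNames(list(truth), gene))
  if (level == "locus") rep$loci$CR
  else rep$alleles$CR[rep$alleles$allele == allele]
}

#' Frequency-binned aggregation of allele-level accuracies
#'
#' Se, PPV and CR are aggregated as frequency-weighted arithmetic means; r2 is
#' aggregated on the signed correlation via Fisher z-transformation (weighted
#' mean of atanh(r), back-transformed, then squared). Undefined entries are
#' excluded and counted.
#'
#' @param report an \code{\link{accuracy_report}}.
#' @param freq_bins upper bin edges on allele frequency (default the
#'   presentation grid 0.5\%, 1\%, 2\%, 5\%, 10\%, 50\%, 100\%).
#' @return data.frame of binned aggregates (plus an \code{"all"} row).
#' @export
aggregate_metrics <- function(report,
                              freq_bins = c(0.005, 0.01, 0.02, 0.05, 0.1,
                                            0.5, 1)) {
  tb <- report$alleles
  tb <- tb[tb$m > 0, , drop = FALSE]
  edges <- c(0, freq_bins)
  out <- NULL
  groups <- c(lapply(seq_along(freq_bins), function(k)
    which(tb$freq > edges[k] & tb$freq <= edges[k + 1])), list(seq_len(nrow(tb))))
  labels <- c(sprintf("(%g,%g]", edges[-length(edges)], freq_bins), "all")
  for (k in seq_along(groups)) {
    idx <- groups[[k]]
    if (!length(idx)) next
    s <- tb[idx, , drop = FALSE]
    wmean <- function(v) {
      ok <- !is.na(v)
      if (!any(ok)) return(NA_real_)
      sum(v[ok] * s$freq[ok]) / sum(s$freq[ok])
    }
    okr <- !is.na(s$r)
    r2agg <- if (any(okr)) {
      z <- atanh(pmin(pmax(s$r[okr], -1 + 1e-12), 1 - 1e-12))
      tanh(sum(z * s$freq[okr]) / sum(s$freq[okr]))^2
    } else NA_real_
    out <- rbind(out, data.frame(
      bin = labels[k], n_alleles = length(idx), Se = wmean(s$Se),
      PPV = wmean(s$PPV), r2 = r2agg, CR = wmean(s$CR),
      n_r2_undefined = sum(!okr), stringsAsFactors = FALSE))
  }
  out
}

#' Subset a panel to chosen samples
#'
#' Keeps both haplotypes of each chosen sample, with labels and any
#' population assignment.
#'
#' @param panel a \code{\link{phased_panel}}.
#' @param samples integer sample indices.
#' @return The subset \code{\link{phased_panel}}.
#' @export
panel_subset <- function(panel, samples) {
  hap <- sort(c(2L * samples - 1L, 2L * samples))
  labs <- lapply(panel$hla_labels, function(by_res)
    lapply(by_res, function(v) v[hap]))
  out <- phased_panel(panel$variants, panel$haplotypes[hap, , drop = FALSE],
                      panel$sample_ids[samples], labs, panel$gene_pos)
  if (!is.null(attr(panel, "population")))
    attr(out, "population") <- attr(panel, "population")[samples]
  out
}

#' 1-nearest-haplotype baseline imputer
#'
#' Assigns each target haplotype the allele of its nearest training haplotype
#' by Hamming distance over the window SNVs; distance ties average the tied
#' neighbours' allele indicators.
#'
#' @param panel_train labeled training \code{\link{phased_panel}}.
#' @param target target panel or 0/1 haplotype matrix.
#' @param group a \code{\link{gene_group}}.
#' @param resolution output resolution.
#' @return An \code{allele_probs} object.
#' @export
baseline_knn_impute <- function(panel_train, target, group, resolution = 4L) {
  sel <- panel_train$variants$pos_bp >= group$span[1] &
    panel_train$variants$pos_bp <= group$span[2]
  if (!any(sel)) stop("group '", group$name, "': no SNVs inside its window")
  ids <- panel_train$variants$id[sel]
  R <- panel_train$haplotypes[, sel, drop = FALSE]
  Tm <- if (inherits(target, "phased_panel"))
    target$haplotypes[, match(ids, target$variants$id), drop = FALSE]
  else as.matrix(target)[, match(ids, colnames(target)), drop = FALSE]
  if (any(is.na(Tm))) stop("target lacks window SNVs required by the baseline")
  dist <- outer(rowSums(Tm), rowSums(R), "+") - 2 * tcrossprod(Tm, R)
  out <- list()
  for (g in group$genes) {
    labs <- resolve_labels(panel_train, g, resolution)
    if (is.null(labs)) next
    lev <- sort(unique(labs))
    onehot <- outer(labs, lev, "==") * 1
    pr <- t(apply(dist, 1L, function(d) {
      nn <- which(d == min(d))
      colMeans(onehot[nn, , drop = FALSE])
    }))
    colnames(pr) <- lev
    out[[g]] <- pr
  }
  sample_ids <- if (inherits(target, "phased_panel")) target$sample_ids
  else NULL
  allele_probs(out, sample_ids)
}

#' K-fold cross-validated imputation accuracy
#'
#' Sample-level folds; within each round the early-stopping sub-validation
#' split is drawn from the training fold only (it is the fitting function's
#' own split of the data it is handed). Held-out probabilities are pooled
#' across folds before metric computation, and allele frequencies are taken
#' from the full panel.
#'
#' @param panel labeled \code{\link{phased_panel}}.
#' @param groups list of \code{\link{gene_group}}s.
#' @param k number of folds (default 10).
#' @param hp a \code{\link{model_hyperparams}}.
#' @param resolution output resolution.
#' @param method \code{"cnn"} (the convolutional model) or \code{"knn"}
#'   (the 1-nearest-haplotype baseline).
#' @param seed fold-assignment seed.
#' @return List with the pooled \code{\link{accuracy_report}} (\code{report}),
#'   pooled \code{allele_probs} (\code{probs}) and the fold assignment.
#' @export
cross_validate <- function(panel, groups, k = 10L, hp = model_hyperparams(),
                           resolution = 4L, method = c("cnn", "knn"),
                           seed = 1L) {
  method <- match.arg(method)
  n <- length(panel$sample_ids)
  if (n < k) stop("need at least k samples")
  folds <- with_seed(sub_seed(seed, "cv_folds"),
                     sample(rep_len(seq_len(k), n)))
  pooled <- list()
  for (fold in seq_len(k)) {
    test_s <- which(folds == fold)
    train <- panel_subset(panel, which(folds != fold))
    test <- panel_subset(panel, test_s)
    test_hap <- rep(2L * test_s, each = 2L) - c(1L, 0L)
    for (gr in groups) {
      pr <- if (method == "cnn")
        predict(hla_cnn(train, gr, resolution, hp), mask_hla(test))
      else baseline_knn_impute(train, mask_hla(test), gr, resolution)
      for (g in names(pr)) {
        if (is.null(pooled[[g]])) {
          pooled[[g]] <- matrix(0, 2L * n, ncol(pr[[g]]),
                                dimnames = list(NULL, colnames(pr[[g]])))
        }
        # fold-specific allele sets can differ; align by name
        miss <- setdiff(colnames(pr[[g]]), colnames(pooled[[g]]))
        if (length(miss)) {
          pooled[[g]] <- cbind(pooled[[g]],
                               matrix(0, nrow(pooled[[g]]), length(miss),
                                      dimnames = list(NULL, miss)))
        }
        pooled[[g]][test_hap, colnames(pr[[g]])] <- unclass(pr)[[g]]
      }
    }
  }
  pooled <- lapply(pooled, function(p) {
    p[, order(colnames(p)), drop = FALSE]
  })
  probs <- structure(pooled, class = "allele_probs",
                     sample_ids = panel$sample_ids)
  truth <- list(); freq <- list()
  for (g in names(pooled)) {
    truth[[g]] <- truth_genotypes(panel, g, resolution)
    labs <- resolve_labels(panel, g, resolution)
    ok <- !(labs %in% c("unknown", "inconsistent"))
    freq[[g]] <- table(labs[ok]) / sum(ok)
  }
  list(report = accuracy_report(probs, truth, freq), probs = probs,
       folds = folds)
}
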