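#' LD profile of a classical allele
#'
#' Squared Pearson correlation between the binary allele indicator and each
#' SNV alt-allele indicator across the panel haplotypes, ordered by physical
#' distance from the gene's representative coordinate (bilateral merge).
#' Monomorphic SNVs get r2 = 0 with a flag.
#'
#' @param panel labeled \code{\link{phased_panel}}.
#' @param gene,allele the target classical allele.
#' @param resolution label resolution to match \code{allele} at.
#' @param window \code{"bilateral_rank"} with \code{k} SNVs, or a
#'   \code{\link{gene_group}} whose span restricts the SNVs (model window).
#' @param k number of nearest SNVs kept for the rank window (default 1000).
#' @return Object of class \code{ld_profile}: data.frame sorted by distance
#'   with columns id, pos_bp, dist_bp, r2, monomorphic.
#' @export
ld_profile <- function(panel, gene, allele, resolution = 4L,
                       window = "bilateral_rank", k = 1000L) {
  labs <- resolve_labels(panel, gene, resolution)
  if (is.null(labs)) stop("gene ", gene, " untyped")
  ind <- as.numeric(labs == allele)
  if (sum(ind) < 2) stop("allele ", allele, " present on < 2 haplotypes")
  pos0 <- panel$gene_pos[[gene]]
  if (is.null(pos0) || is.na(pos0)) stop("no representative position for ",
                                         gene)
  keep <- seq_len(nrow(panel$variants))
  if (inherits(window, "gene_group"))
    keep <- which(panel$variants$pos_bp >= window$span[1] &
                    panel$variants$pos_bp <= window$span[2])
  d <- abs(panel$variants$pos_bp[keep] - pos0)
  ord <- keep[order(d)]
  if (identical(window, "bilateral_rank")) ord <- ord[seq_len(min(k, length(ord)))]
  H <- panel$haplotypes[, ord, drop = FALSE]
  mono <- apply(H, 2L, function(v) stats::sd(v) == 0)
  r2 <- numeric(ncol(H))
  if (stats::sd(ind) > 0)
    r2[!mono] <- suppressWarnings(
      as.numeric(stats::cor(ind, H[, !mono, drop = FALSE]))^2)
  out <- data.frame(id = panel$variants$id[ord],
                    pos_bp = panel$variants$pos_bp[ord],
                    dist_bp = abs(panel$variants$pos_bp[ord] - pos0),
                    r2 = r2, monomorphic = mono, stringsAsFactors = FALSE)
  structure(list(gene = gene, allele = allele, pos_bp = pos0, snv_r2 = out),
            class = "ld_profile")
}

#' AUC of distance-dependent LD decay
#'
#' SNVs are ranked by increasing distance from the allele; the cumulative r2
#' curve over rank is normalized to [0,1] on both axes (rank / window size,
#' cumulative r2 / total r2) and integrated by the trapezoid rule through the
#' origin. Distance-dependent decay makes the curve convex upward and the AUC
#' exceed the 0.5 of a flat (uniform-r2) profile.
#'
#' @param profile an \code{\link{ld_profile}}.
#' @return AUC in [0,1]; NA (flagged by a warning) when total r2 is 0.
#' @export
auc_ld_decay <- function(profile) {
  r2 <- profile$snv_r2$r2
  W <- length(r2)
  tot <- sum(r2)
  if (tot <= 0) { warning("total r2 is zero; AUC undefined"); return(NA_real_) }
  y <- c(0, cumsum(r2) / tot)
  x <- c(0, seq_len(W) / W)
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

#' Maximum LD within the k nearest SNVs
#'
#' @param profile an \code{\link{ld_profile}}.
#' @param k number of nearest SNVs considered bilaterally (default 100).
#' @return Maximum r2 among the k nearest SNVs.
#' @export
max_ld_within <- function(profile, k = 100L) {
  max(profile$snv_r2$r2[seq_len(min(k, nrow(profile$snv_r2)))])
}

#' Regression of allele-level accuracy on LD-decay AUC
#'
#' Ordinary least squares of an allele-level accuracy metric on the LD-decay
#' AUC, adjusted for allele frequency (with intercept).
#'
#' @param metric,auc,freq numeric vectors over alleles.
#' @return lm-style coefficient table (estimate, SE, t, p).
#' @export
accuracy_vs_ld_regression <- function(metric, auc, freq) {
  ok <- stats::complete.cases(metric, auc, freq)
  if (sum(ok) < 3) stop("need at least 3 alleles with defined values")
  fit <- stats::lm(metric[ok] ~ auc[ok] + freq[ok])
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design")
  ct <- summary(fit)$coefficients
  rownames(ct) <- c("(Intercept)", "auc", "freq")
  ct
}

#' SmoothGrad sensitivity map of an allele
#'
#' For every carrier haplotype, adds Gaussian noise to the (continuously
#' relaxed) one-hot SNV encoding \code{n} times, computes the absolute input
#' gradient of the allele's cross-entropy loss, averages over noise draws and
#' sums over the two one-hot channels; the final map averages over carriers.
#'
#' @param model fitted \code{\link{hla_cnn}}.
#' @param panel labeled panel supplying carrier haplotypes.
#' @param gene,allele target allele.
#' @param n noise samples per haplotype (default 200).
#' @param noise_sd Gaussian noise SD on the one-hot scale (default 0.1).
#' @param seed noise seed.
#' @return Object of class \code{sensitivity_map}: data.frame (variant id,
#'   pos, sensitivity) plus metadata.
#' @export
smoothgrad <- function(model, panel, gene, allele, n = 200L, noise_sd = 0.1,
                       seed = 1L) {
  labs <- resolve_labels(panel, gene, model$resolution)
  carriers <- which(labs == allele)
  if (!length(carriers)) stop("no carrier haplotypes of ", gene, "*", allele)
  hap <- panel$haplotypes[carriers, , drop = FALSE]
  rownames(hap) <- NULL
  X <- align_target(model, hap)
  W <- dim(X)[2]; H <- dim(X)[3]
  acc <- matrix(0, W, H)
  with_seed(sub_seed(seed, "smoothgrad"), {
    for (s in seq_len(n)) {
      Xn <- X + array(stats::rnorm(length(X), 0, noise_sd), dim(X))
      gmap <- input_gradient(model, Xn, gene, allele)   # (2, W, H)
      acc <- acc + apply(abs(gmap), c(2L, 3L), sum)
    }
  })
  sens <- rowMeans(acc / n)
  pos <- panel$variants$pos_bp[match(model$variant_ids, panel$variants$id)]
  structure(list(gene = gene, allele = allele, n_noise = n,
                 noise_sd = noise_sd, n_haplotypes = H,
                 map = data.frame(id = model$variant_ids, pos_bp = pos,
                                  sensitivity = sens,
                                  stringsAsFactors = FALSE)),
            class = "sensitivity_map")
}

#' Entropy of MC-dropout sampling variation
#'
#' Binary entropy (natural log) of the agreement between stochastic forward
#' passes and the deterministic best-guess genotype:
#' \code{H = -(t/T log(t/T) + (1 - t/T) log(1 - t/T))}, with
#' \code{0 log 0 = 0}, so H is zero iff t = 0 or t = T and maximal (log 2)
#' at t = T/2.
#'
#' @param t number of passes matching the best guess.
#' @param T total number of passes.
#' @return Entropy in nats.
#' @export
mc_entropy <- function(t, T) {
  stopifnot(all(t >= 0), all(t <= T), all(T >= 1))
  p <- t / T
  xlogx <- function(q) ifelse(q == 0, 0, q * log(q))
  -(xlogx(p) + xlogx(1 - p))
}

#' ROC-AUC for discriminating incorrectly imputed genotypes
#'
#' Ranks per-(individual, gene) scores against correctness labels; the AUC is
#' the probability that an incorrect genotype receives a higher score than a
#' correct one (midrank convention for ties; equivalent to the Mann-Whitney
#' statistic). Entropy scores are used as-is (higher = more uncertain);
#' dosage-based scores should be supplied as the negative best-guess genotype
#' probability so that higher also means more suspect.
#'
#' @param scores numeric vector.
#' @param incorrect logical vector (TRUE = genotype imputed incorrectly).
#' @return ROC-AUC in [0,1]; NA with a warning if one class is absent.
#' @export
uncertainty_roc <- function(scores, incorrect) {
  stopifnot(length(scores) == length(incorrect))
  n1 <- sum(incorrect); n0 <- sum(!incorrect)
  if (n1 == 0 || n0 == 0) {
    warning("both correct and incorrect genotypes required; AUC undefined")
    return(NA_real_)
  }
  r <- rank(scores)                      # midranks
  (sum(r[incorrect]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Dosage-based discrimination score
#'
#' Negative posterior probability of the best-guess diploid genotype (product
#' of the two haplotypes' maximal allele probabilities), the comparator for
#' entropy-based uncertainty.
#'
#' @param probs an \code{allele_probs} object.
#' @param gene gene name.
#' @return Numeric vector, one score per individual (higher = more suspect).
#' @export
dosage_discrimination_score <- function(probs, gene) {
  p <- unclass(probs)[[gene]]
  mx <- apply(p, 1L, max)
  -(mx[c(TRUE, FALSE)] * mx[c(FALSE, TRUE)])
}
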