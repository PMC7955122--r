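#' Post-imputation r2 filter
#'
#' Keeps markers whose cross-validated dosage r2 meets the threshold
#' (inclusive: r2 = 0.7 is kept). Markers with undefined r2 are dropped.
#'
#' @param report an \code{\link{accuracy_report}} from cross-validation.
#' @param threshold minimum r2 (default 0.7).
#' @return data.frame of surviving report rows (gene, allele, r2, ...).
#' @export
filter_by_cv_r2 <- function(report, threshold = 0.7) {
  tb <- report$alleles
  tb[!is.na(tb$r2) & tb$r2 >= threshold, , drop = FALSE]
}

#' Logistic dosage association
#'
#' Additive logistic regression of case status on one or more dosage columns,
#' adjusted for covariates, fitted by iteratively reweighted least squares.
#' Columns aliased with the rest of the design are dropped (and reported);
#' quasi-complete separation is flagged and Wald statistics suppressed for the
#' affected terms.
#'
#' @param dosage numeric vector or matrix (the tested columns).
#' @param phenotype 0/1 vector.
#' @param covariates optional numeric matrix (no intercept column).
#' @return Object of class \code{hla_logit}: coefficient table for the tested
#'   terms, log-likelihood, convergence and separation flags, dropped columns.
#' @export
logistic_fit <- function(dosage, phenotype, covariates = NULL) {
  X <- as.matrix(dosage)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("dose", seq_len(ncol(X)))
  n <- length(phenotype)
  stopifnot(nrow(X) == n, all(phenotype %in% 0:1))
  design <- cbind(`(Intercept)` = 1, covariates, X)
  qrd <- qr(design)
  dropped <- character(0)
  if (qrd$rank < ncol(design)) {
    keep <- qrd$pivot[seq_len(qrd$rank)]
    dropped <- colnames(design)[-keep]
    design <- design[, sort(keep), drop = FALSE]
  }
  fit <- suppressWarnings(
    stats::glm.fit(design, phenotype, family = stats::binomial(),
                   control = list(epsilon = 1e-12, maxit = 100L)))
  beta <- fit$coefficients
  w <- fit$weights
  XtWX <- crossprod(design * sqrt(w))
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, length(beta)) else sqrt(diag(cov))
  separated <- abs(beta) > 15 | !is.finite(se) | se > 100
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  ll <- -fit$deviance / 2
  tested <- intersect(colnames(X), colnames(design))
  tab <- data.frame(term = names(beta), beta = beta, se = se, z = z, p = p,
                    separated = separated, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(coefficients = tab, loglik = ll,
                 converged = fit$converged, tested = tested,
                 dropped = dropped, n = n,
                 n_cases = sum(phenotype == 1), n_controls = sum(phenotype == 0),
                 design_rank = qr(design)$rank),
            class = "hla_logit")
}

#' @export
print.hla_logit <- function(x, ...) {
  cat("Logistic dosage association (", x$n_cases, "cases /", x$n_controls,
      "controls )\n")
  print(x$coefficients[x$coefficients$term %in% x$tested, , drop = FALSE],
        row.names = FALSE)
  if (length(x$dropped)) cat("Aliased columns dropped:",
                             paste(x$dropped, collapse = ", "), "\n")
  if (!x$converged) cat("WARNING: IRLS did not converge\n")
  invisible(x)
}

# Wald p for a single tested dosage column (helper for the stepwise scan)
wald_p <- function(fit) {
  if (!length(fit$tested)) return(NA_real_)
  tab <- fit$coefficients
  row <- tab[tab$term == fit$tested[1], , drop = FALSE]
  if (!nrow(row) || row$separated) return(NA_real_)
  row$p
}

#' Omnibus association test of a multiallelic amino-acid position
#'
#' Likelihood-ratio test comparing the null model (covariates plus any
#' conditioning columns) against the model additionally containing the
#' position's k-1 residue dosage columns, the most frequent residue serving as
#' the reference; the statistic is chi-square with k-1 degrees of freedom.
#'
#' @param residues individuals x residues dosage matrix for one position.
#' @param phenotype 0/1 vector.
#' @param covariates optional covariate matrix.
#' @param conditioning optional matrix of conditioning dosage columns.
#' @param reference reference residue name; default the most frequent residue
#'   (by total dosage) — supply the reference-cohort choice for trans-ethnic
#'   runs.
#' @return List with p_value, df, the residue effect table and the reference.
#' @export
omnibus_test <- function(residues, phenotype, covariates = NULL,
                         conditioning = NULL, reference = NULL) {
  residues <- as.matrix(residues)
  if (ncol(residues) < 2L)
    return(list(p_value = NA_real_, df = 0L,
                note = "single residue after filtering; test skipped"))
  if (is.null(reference))
    reference <- colnames(residues)[which.max(colSums(residues))]
  keep <- setdiff(colnames(residues), reference)
  base <- cbind(covariates, conditioning)
  null_des <- cbind(`(Intercept)` = rep(1, length(phenotype)), base)
  nqr <- qr(null_des)
  if (nqr$rank < ncol(null_des))
    null_des <- null_des[, sort(nqr$pivot[seq_len(nqr$rank)]), drop = FALSE]
  fit0 <- suppressWarnings(
    stats::glm.fit(null_des, phenotype, family = stats::binomial(),
                   control = list(epsilon = 1e-12, maxit = 100L)))
  fit1 <- logistic_fit(residues[, keep, drop = FALSE], phenotype, base)
  df <- length(setdiff(keep, fit1$dropped))
  if (df < 1L)
    return(list(p_value = NA_real_, df = 0L,
                note = "all residue columns aliased"))
  lrt <- 2 * (fit1$loglik - (-fit0$deviance / 2))
  list(p_value = stats::pchisq(max(lrt, 0), df = df, lower.tail = FALSE),
       df = df, reference = reference,
       coefficients = fit1$coefficients[
         fit1$coefficients$term %in% keep, , drop = FALSE])
}

#' Conditioning covariate columns for a selected signal
#'
#' Gene targets contribute all the gene's 4-digit classical allele dosage
#' columns minus one reference (the most frequent, dropped to avoid exact
#' collinearity with the intercept); position targets contribute the
#' position's k-1 residue columns; variant targets their single column.
#'
#' @param dt a \code{\link{dosage_table}} holding the cohort dosages.
#' @param type \code{"gene"}, \code{"position"} or \code{"variant"}.
#' @param gene gene name (gene/position targets).
#' @param position amino-acid position (position targets).
#' @param id column id (variant targets).
#' @return Character vector of conditioning column ids.
#' @export
conditioning_set <- function(dt, type = c("gene", "position", "variant"),
                             gene = NULL, position = NULL, id = NULL) {
  type <- match.arg(type)
  info <- dt$info
  if (type == "variant") return(id)
  if (type == "gene") {
    cols <- info$id[info$gene == gene & info$class == "classical_allele"]
    if (length(cols) < 2L) return(cols)
    ref <- cols[which.max(colSums(dt$dosages[, cols, drop = FALSE]))]
    return(setdiff(cols, ref))
  }
  cols <- info$id[info$gene == gene & info$class == "residue_binary" &
                    info$position == position]
  if (length(cols) < 2L) return(cols)
  ref <- cols[which.max(colSums(dt$dosages[, cols, drop = FALSE]))]
  setdiff(cols, ref)
}

# scan units: one binary unit per classical allele column, one omnibus unit
# per amino-acid position (k >= 2 residues)
scan_units <- function(dt) {
  info <- dt$info
  units <- list()
  for (j in which(info$class %in% c("classical_allele", "snv")))
    units[[info$id[j]]] <- list(id = info$id[j], test = "binary",
                                gene = info$gene[j], cols = info$id[j])
  pos_tab <- unique(info[info$class == "residue_binary",
                         c("gene", "position")])
  for (k in seq_len(nrow(pos_tab))) {
    g <- pos_tab$gene[k]; pos <- pos_tab$position[k]
    cols <- info$id[info$gene == g & info$class == "residue_binary" &
                      info$position == pos]
    uid <- paste0(g, ":pos", pos)
    units[[uid]] <- list(id = uid, test = "omnibus", gene = g,
                         position = pos, cols = cols)
  }
  units[order(names(units))]
}

#' Forward stepwise conditional association analysis
#'
#' Each round scans every remaining variant (binary Wald test for biallelic
#' markers, omnibus LRT for multiallelic amino-acid positions) conditional on
#' the accumulated conditioning set, selects the smallest p-value and, if it
#' passes the genome-wide threshold, adds the selected signal's conditioning
#' columns and iterates; otherwise it stops. Within the designated tight-LD
#' gene region the conditioning set grows by the selected variant's own
#' columns; outside it, by all 4-digit alleles of the selected signal's gene.
#'
#' @param dt a \code{\link{dosage_table}} (classical alleles and residues).
#' @param phenotype 0/1 vector.
#' @param covariates optional covariate matrix.
#' @param threshold significance threshold (default 5e-8).
#' @param tight_ld_genes genes where conditioning stays variant-level
#'   (default \code{c("HLA-DRB1", "HLA-DQA1", "HLA-DQB1")}).
#' @return Object of class \code{finemap_state}: list of rounds (selected
#'   signal, p, conditioning added, full scan table) and the stopping reason.
#' @export
stepwise_conditional <- function(dt, phenotype, covariates = NULL,
                                 threshold = 5e-8,
                                 tight_ld_genes = c("HLA-DRB1", "HLA-DQA1",
                                                    "HLA-DQB1")) {
  units <- scan_units(dt)
  if (!length(units))
    return(structure(list(rounds = list(), reason = "no variants"),
                     class = "finemap_state"))
  cond_cols <- character(0)
  remaining <- names(units)
  rounds <- list()
  repeat {
    if (!length(remaining)) { reason <- "no remaining variants"; break }
    cond <- if (length(cond_cols))
      dt$dosages[, cond_cols, drop = FALSE] else NULL
    scan <- data.frame(id = remaining, test = NA_character_, p = NA_real_,
                       stringsAsFactors = FALSE)
    for (i in seq_along(remaining)) {
      u <- units[[remaining[i]]]
      scan$test[i] <- u$test
      if (u$test == "binary") {
        fit <- logistic_fit(dt$dosages[, u$cols, drop = FALSE], phenotype,
                            cbind(covariates, cond))
        if (u$cols %in% fit$dropped) next      # aliased with conditioning
        scan$p[i] <- wald_p(fit)
      } else {
        ot <- omnibus_test(dt$dosages[, u$cols, drop = FALSE], phenotype,
                           covariates, cond)
        scan$p[i] <- ot$p_value
      }
    }
    ok <- which(!is.na(scan$p))
    if (!length(ok)) { reason <- "all tests undefined"; break }
    top <- ok[order(scan$p[ok], scan$id[ok])][1]   # ties broken by name
    if (scan$p[top] >= threshold) {
      reason <- sprintf("top p %.3g above threshold %.1g", scan$p[top],
                        threshold)
      rounds[[length(rounds) + 1L]] <- list(selected = NA_character_,
                                            p = scan$p[top],
                                            conditioning_added = character(0),
                                            scan = scan)
      break
    }
    u <- units[[scan$id[top]]]
    add <- if (u$gene %in% tight_ld_genes) {
      if (u$test == "omnibus")
        conditioning_set(dt, "position", gene = u$gene,
                         position = u$position)
      else conditioning_set(dt, "variant", id = u$cols)
    } else conditioning_set(dt, "gene", gene = u$gene)
    add <- setdiff(add, cond_cols)
    cond_cols <- c(cond_cols, add)
    rounds[[length(rounds) + 1L]] <- list(selected = u$id, p = scan$p[top],
                                          test = u$test,
                                          conditioning_added = add,
                                          scan = scan)
    # once a gene is conditioned at gene level, its own units are exhausted
    remaining <- setdiff(remaining, u$id)
    if (!(u$gene %in% tight_ld_genes))
      remaining <- setdiff(remaining, names(Filter(function(x)
        x$gene == u$gene, units)))
  }
  structure(list(rounds = rounds, reason = reason,
                 n_signals = sum(vapply(rounds, function(r)
                   !is.na(r$selected %||% NA_character_), TRUE))),
            class = "finemap_state")
}

#' @export
print.finemap_state <- function(x, ...) {
  sel <- Filter(function(r) !is.na(r$selected %||% NA), x$rounds)
  cat("Stepwise conditional analysis:", length(sel), "signal(s)\n")
  for (i in seq_along(sel))
    cat(sprintf("  round %d: %s (%s test, p = %.3g)\n", i, sel[[i]]$selected,
                sel[[i]]$test, sel[[i]]$p))
  cat("Stopped:", x$reason, "\n")
  invisible(x)
}

#' Merge cohorts for trans-ethnic analysis
#'
#' HLA alleles and residues are taken as the union across cohorts, with
#' dosage 0 for individuals of a cohort where the marker is absent; SNV
#' columns are intersected and palindromic SNVs (A/T, C/G) removed.
#' Principal-component covariates become block-diagonal (zero-filled for the
#' other cohorts) and population indicator columns are appended; other
#' covariates (e.g. sex) are concatenated.
#'
#' @param cohorts list of \code{hla_cohort} objects with distinct populations.
#' @return A merged \code{hla_cohort} with population labels per individual.
#' @export
transethnic_merge <- function(cohorts) {
  stopifnot(length(cohorts) >= 2L)
  ids <- unlist(lapply(cohorts, `[[`, "sample_ids"))
  if (anyDuplicated(ids)) stop("duplicate sample ids across cohorts")
  # SNV handling: intersect and drop palindromic pairs
  is_palindromic <- function(ref, alt)
    (ref == "A" & alt == "T") | (ref == "T" & alt == "A") |
    (ref == "C" & alt == "G") | (ref == "G" & alt == "C")
  snv_sets <- lapply(cohorts, function(ch) {
    info <- ch$dosages$info
    info$id[info$class == "snv"]
  })
  snv_keep <- Reduce(intersect, snv_sets)
  info1 <- cohorts[[1]]$dosages$info
  if (length(snv_keep) && all(c("ref", "alt") %in% names(info1))) {
    i <- match(snv_keep, info1$id)
    snv_keep <- snv_keep[!is_palindromic(info1$ref[i], info1$alt[i])]
  }
  hla_ids <- unique(unlist(lapply(cohorts, function(ch) {
    info <- ch$dosages$info
    info$id[info$class != "snv"]
  })))
  all_ids <- c(hla_ids, snv_keep)
  n_tot <- sum(vapply(cohorts, function(ch) length(ch$phenotype), 0L))
  D <- matrix(0, n_tot, length(all_ids),
              dimnames = list(NULL, all_ids))
  info <- NULL
  row0 <- 0L
  pc_blocks <- list(); sex <- numeric(0); pheno <- integer(0)
  pop <- character(0)
  for (ch in cohorts) {
    nc <- length(ch$phenotype)
    idx <- row0 + seq_len(nc)
    present <- intersect(colnames(ch$dosages$dosages), all_ids)
    D[idx, present] <- ch$dosages$dosages[, present, drop = FALSE]
    new_rows <- ch$dosages$info[match(setdiff(present, info$id),
                                      ch$dosages$info$id), , drop = FALSE]
    info <- rbind(info, new_rows)
    cv <- ch$covariates
    pcs <- cv[, grepl("^pc", colnames(cv)), drop = FALSE]
    colnames(pcs) <- paste(colnames(pcs), ch$population, sep = "_")
    pc_blocks[[ch$population]] <- list(idx = idx, pcs = pcs)
    sex <- c(sex, cv[, "sex"])
    pheno <- c(pheno, ch$phenotype)
    pop <- c(pop, rep(ch$population, nc))
    row0 <- row0 + nc
  }
  info <- info[match(all_ids, info$id), , drop = FALSE]
  pc_mat <- NULL
  for (b in pc_blocks) {
    blk <- matrix(0, n_tot, ncol(b$pcs), dimnames = list(NULL,
                                                         colnames(b$pcs)))
    blk[b$idx, ] <- b$pcs
    pc_mat <- cbind(pc_mat, blk)
  }
  pops <- unique(pop)
  pop_ind <- sapply(pops[-1], function(p) as.numeric(pop == p))
  if (is.null(dim(pop_ind))) pop_ind <- matrix(pop_ind, ncol = length(pops) - 1)
  colnames(pop_ind) <- paste0("pop_", pops[-1])
  covs <- cbind(sex = sex, pc_mat, pop_ind)
  structure(list(dosages = dosage_table(D, info), phenotype = pheno,
                 covariates = covs, population = pop, sample_ids = ids),
            class = "hla_cohort")
}

#' Liability-scale variance explained by HLA variants
#'
#' Maps the observed-scale variance explained by the fitted multivariate
#' linear predictor onto the liability scale via the threshold-model
#' transformation with ascertainment correction
#' (\code{R2_liability = R2_observed * K^2 (1-K)^2 / (z^2 P (1-P))}, where K
#' is the population prevalence, P the sample case fraction, and z the
#' standard-normal density at the liability threshold).
#'
#' @param betas named vector of fitted log-odds effects.
#' @param dosages matrix of the corresponding dosage columns.
#' @param phenotype 0/1 vector.
#' @param prevalence population prevalence K in (0,1).
#' @return Proportion of liability variance explained.
#' @export
variance_explained <- function(betas, dosages, phenotype, prevalence) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  X <- as.matrix(dosages)[, names(betas), drop = FALSE]
  score <- as.numeric(X %*% betas)
  if (stats::sd(score) == 0) return(0)
  r2_obs <- stats::cor(score, phenotype)^2
  K <- prevalence; P <- mean(phenotype)
  z <- stats::dnorm(stats::qnorm(1 - K))
  r2_obs * K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
}
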