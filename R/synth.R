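#' Configuration for the synthetic phased-panel simulator
#'
#' The simulator emulates the statistical structure an HLA imputation model
#' consumes: haplotype clusters (one SNV backbone per classical allele),
#' tunable SNV-tagging fidelity, a recombination-style mosaic along the map,
#' skewed allele-frequency spectra with rare alleles, hierarchical 2/4-digit
#' allele labels, an amino-acid dictionary separating every allele pair, and
#' optional two-population structure.
#'
#' @param n_haplotypes total haplotypes (two per sample, even).
#' @param n_snvs_per_group SNVs per gene group.
#' @param groups list of \code{list(name=, genes=)} describing synthetic groups.
#' @param alleles_per_gene named integer vector (4-digit alleles per gene).
#' @param freq_spectrum Dirichlet concentration (scalar; < 1 gives a skewed
#'   spectrum) or a named list of explicit per-gene frequency vectors.
#' @param tagging_fidelity probability phi that a haplotype is built from its
#'   own allele's backbone rather than a random one.
#' @param snv_noise_rate per-SNV independent flip rate epsilon.
#' @param recomb_switch_rate per-interval probability rho of switching the
#'   donor backbone while walking along the map.
#' @param n_populations 1 or 2.
#' @param pop_divergence SD of the logit-normal perturbation applied to allele
#'   frequencies in the second population.
#' @param n_private_alleles number of alleles per gene made private to one
#'   population (frequency zero in the other).
#' @param tag_placement where allele-distinguishing SNVs sit relative to the
#'   gene: \code{"uniform"} (fully random backbones), \code{"near"} or
#'   \code{"far"} (shared backbone except tag SNVs adjacent to the gene or at
#'   the window edges).
#' @param n_tag_snvs number of distinguishing SNVs per gene when
#'   \code{tag_placement} is \code{"near"}/\code{"far"}.
#' @param resolutions label resolutions to emit (subset of c(2, 4, 6)).
#' @param seed master seed; all randomness derives from it.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_haplotypes = 400L,
                       n_snvs_per_group = 60L,
                       groups = list(list(name = "grp1",
                                          genes = c("G1", "G2"))),
                       alleles_per_gene = NULL,
                       freq_spectrum = 0.8,
                       tagging_fidelity = 0.95,
                       snv_noise_rate = 0.02,
                       recomb_switch_rate = 0.01,
                       n_populations = 1L,
                       pop_divergence = 0.5,
                       n_private_alleles = 0L,
                       tag_placement = c("uniform", "near", "far"),
                       n_tag_snvs = 10L,
                       resolutions = c(2L, 4L),
                       seed = 1L) {
  tag_placement <- match.arg(tag_placement)
  genes <- unlist(lapply(groups, `[[`, "genes"))
  if (is.null(alleles_per_gene))
    alleles_per_gene <- stats::setNames(rep(4L, length(genes)), genes)
  stopifnot(n_haplotypes %% 2L == 0L, n_haplotypes >= 4L,
            tagging_fidelity >= 0, tagging_fidelity <= 1,
            snv_noise_rate >= 0, snv_noise_rate < 1,
            recomb_switch_rate >= 0, recomb_switch_rate <= 1,
            n_populations %in% 1:2, all(resolutions %in% c(2L, 4L, 6L)))
  if (is.list(freq_spectrum))
    for (g in names(freq_spectrum))
      if (abs(sum(freq_spectrum[[g]]) - 1) > 1e-8)
        stop("explicit frequencies for ", g, " must sum to 1")
  structure(list(n_haplotypes = as.integer(n_haplotypes),
                 n_snvs_per_group = as.integer(n_snvs_per_group),
                 groups = groups, alleles_per_gene = alleles_per_gene,
                 freq_spectrum = freq_spectrum,
                 tagging_fidelity = tagging_fidelity,
                 snv_noise_rate = snv_noise_rate,
                 recomb_switch_rate = recomb_switch_rate,
                 n_populations = as.integer(n_populations),
                 pop_divergence = pop_divergence,
                 n_private_alleles = as.integer(n_private_alleles),
                 tag_placement = tag_placement,
                 n_tag_snvs = as.integer(n_tag_snvs),
                 resolutions = sort(as.integer(resolutions)),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# hierarchical 4-digit allele names: alleles i grouped pairwise under
# 2-digit parents "01", "02", ...
synth_allele_names <- function(k) {
  parent <- (seq_len(k) + 1L) %/% 2L
  within <- seq_len(k) - 2L * (parent - 1L)
  sprintf("%02d:%02d", parent, within)
}

#' Simulate a phased HLA reference panel
#'
#' @param config a \code{\link{sim_config}}.
#' @return List with elements \code{panel} (a \code{\link{phased_panel}} with
#'   truth labels, plus a per-sample \code{population} attribute in
#'   two-population mode), \code{dictionary} (an \code{aa_dictionary}),
#'   \code{groups} (list of \code{\link{gene_group}}), and \code{tag_snvs}
#'   (the planted distinguishing SNV ids per gene, for diagnostics).
#' @export
simulate_reference_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(sub_seed(config$seed, "panel"), {
    region_len <- 800000L
    all_var <- NULL; gene_pos <- numeric(); groups <- list()
    backbones <- list(); freqs <- list(); tag_ids <- list()
    snv_gene <- character(0)
    for (gi in seq_along(config$groups)) {
      gdef <- config$groups[[gi]]
      start <- (gi - 1L) * 2000000L + 1000000L
      pos <- round(seq(start, start + region_len,
                       length.out = config$n_snvs_per_group))
      ids <- sprintf("rs%d_%d", gi, seq_along(pos))
      ng <- length(gdef$genes)
      gp <- round(start + region_len * (seq_len(ng)) / (ng + 1L))
      names(gp) <- gdef$genes
      gene_pos <- c(gene_pos, gp)
      all_var <- rbind(all_var,
                       data.frame(id = ids, chrom = "6", pos_bp = pos,
                                  ref_allele = "A", alt_allele = "G",
                                  stringsAsFactors = FALSE))
      # each SNV is driven by the nearest gene's allele mosaic
      owner <- gdef$genes[apply(abs(outer(pos, gp, "-")), 1, which.min)]
      snv_gene <- c(snv_gene, owner)
      groups[[gdef$name]] <- gene_group(gdef$name, gdef$genes, gp)
      for (g in gdef$genes) {
        k <- config$alleles_per_gene[[g]]
        mine <- which(owner == g)
        if (!length(mine)) stop("gene ", g, " owns no SNVs; reduce gene count")
        if (config$tag_placement == "uniform") {
          if (2 ^ min(length(mine), 30) < k)
            stop("alleles_per_gene[", g, "] exceeds representable backbones")
          repeat {
            bb <- matrix(stats::rbinom(k * length(mine), 1L, 0.5), k)
            if (!anyDuplicated(bb)) break
          }
          tags <- mine
        } else {
          d <- abs(pos[mine] - gp[[g]])
          ntag <- min(config$n_tag_snvs, length(mine))
          if (2 ^ min(ntag, 30) < k)
            stop("alleles_per_gene[", g, "] exceeds representable backbones")
          sel <- if (config$tag_placement == "near")
            order(d)[seq_len(ntag)] else order(-d)[seq_len(ntag)]
          base <- stats::rbinom(length(mine), 1L, 0.5)
          bb <- matrix(rep(base, each = k), k)
          repeat {
            bb[, sel] <- stats::rbinom(k * ntag, 1L, 0.5)
            if (!anyDuplicated(bb)) break
          }
          tags <- mine[sel]
        }
        colnames(bb) <- ids[mine]
        backbones[[g]] <- bb
        tag_ids[[g]] <- ids[tags]
        # allele frequency spectrum (4-digit)
        f <- if (is.list(config$freq_spectrum)) config$freq_spectrum[[g]]
        else { x <- stats::rgamma(k, shape = config$freq_spectrum); x / sum(x) }
        if (length(f) != k) stop("frequency vector length != allele count")
        freqs[[g]] <- list(f)
        if (config$n_populations == 2L) {
          f2 <- stats::plogis(stats::qlogis(pmin(pmax(f, 1e-6), 1 - 1e-6)) +
                                stats::rnorm(k, 0, config$pop_divergence))
          if (config$n_private_alleles > 0L) {
            priv <- sample(k, min(config$n_private_alleles, k - 1L))
            # alternate privacy between the two populations
            for (ii in seq_along(priv))
              if (ii %% 2L == 1L) f2[priv[ii]] <- 0 else f[priv[ii]] <- 0
            freqs[[g]][[1L]] <- f / sum(f)
          }
          freqs[[g]][[2L]] <- f2 / sum(f2)
        }
      }
    }
    n_hap <- config$n_haplotypes
    pop <- if (config$n_populations == 2L)
      rep(rep(c("pop1", "pop2"), length.out = n_hap / 2L), each = 2L)
    else rep("pop1", n_hap)
    genes <- names(config$alleles_per_gene)
    truth4 <- matrix(NA_character_, n_hap, length(genes),
                     dimnames = list(NULL, genes))
    H <- matrix(0L, n_hap, nrow(all_var))
    colnames(H) <- all_var$id
    for (g in genes) {
      k <- config$alleles_per_gene[[g]]
      anames <- synth_allele_names(k)
      bb <- backbones[[g]]
      cols <- match(colnames(bb), all_var$id)
      for (p in seq_len(config$n_populations)) {
        rows <- which(pop == paste0("pop", p))
        f <- freqs[[g]][[min(p, length(freqs[[g]]))]]
        a_idx <- sample.int(k, length(rows), replace = TRUE, prob = f)
        truth4[rows, g] <- anames[a_idx]
        # donor mosaic: start from own backbone with prob phi, switch with
        # rate rho between adjacent SNVs, then apply per-SNV noise
        for (ri in seq_along(rows)) {
          own <- a_idx[ri]
          donor <- if (stats::runif(1) < config$tagging_fidelity) own
          else sample.int(k, 1L, prob = f)
          hap <- integer(length(cols))
          for (j in seq_along(cols)) {
            if (j > 1L && stats::runif(1) < config$recomb_switch_rate)
              donor <- sample.int(k, 1L, prob = f)
            hap[j] <- bb[donor, j]
          }
          H[rows[ri], cols] <- hap
        }
      }
    }
    if (config$snv_noise_rate > 0) {
      flips <- matrix(stats::rbinom(length(H), 1L, config$snv_noise_rate),
                      nrow(H))
      H <- (H + flips) %% 2L
    }
    hla_labels <- list()
    for (g in genes) {
      hla_labels[[g]] <- list()
      if (2L %in% config$resolutions)
        hla_labels[[g]][["2"]] <- substr(truth4[, g], 1L, 2L)
      if (4L %in% config$resolutions)
        hla_labels[[g]][["4"]] <- truth4[, g]
      if (6L %in% config$resolutions)
        hla_labels[[g]][["6"]] <- paste0(truth4[, g], ":01")
    }
    sample_ids <- sprintf("S%04d", seq_len(n_hap / 2L))
    panel <- phased_panel(all_var, H, sample_ids, hla_labels, gene_pos)
    attr(panel, "population") <- pop[seq(1, n_hap, 2L)]
    dict <- synth_aa_dictionary(config)
    list(panel = panel, dictionary = dict, groups = groups,
         tag_snvs = tag_ids)
  })
}

# residues chosen so every pair of 4-digit alleles differs at >= 1 position:
# position 1 carries the 2-digit parent letter, binary positions encode the
# allele index, one position is fully multiallelic, one is invariant.
synth_aa_dictionary <- function(config) {
  rows <- NULL
  for (g in names(config$alleles_per_gene)) {
    k <- config$alleles_per_gene[[g]]
    anames <- synth_allele_names(k)
    nbits <- max(1L, ceiling(log2(k)))
    for (i in seq_len(k)) {
      res <- c(LETTERS[(i + 1L) %/% 2L],
               ifelse(bitwAnd(i - 1L, 2L ^ (seq_len(nbits) - 1L)) > 0,
                      "R", "K"),
               LETTERS[i], "G")
      rows <- rbind(rows, data.frame(gene = g, allele = anames[i],
                                     position = seq_along(res), residue = res,
                                     stringsAsFactors = FALSE))
    }
  }
  aa_dictionary(rows)
}

#' Mask HLA labels to create a target SNV set
#'
#' @param panel a labeled \code{\link{phased_panel}}.
#' @return The panel with empty \code{hla_labels}; the removed labels are kept
#'   in attribute \code{"truth"} for scoring.
#' @export
mask_hla <- function(panel) {
  truth <- panel$hla_labels
  panel$hla_labels <- list()
  attr(panel, "truth") <- truth
  panel
}

#' Case-control cohort specification
#'
#' @param n_cases,n_controls cohort sizes.
#' @param causal_effects named numeric vector of per-dosage-unit log-odds.
#'   Names address classical alleles as \code{"GENE*ALLELE"} (e.g.
#'   \code{"G1*01:01"}) or residues as \code{"GENE:pos<P>:<residue>"}.
#' @param intercept baseline log-odds.
#' @param covariate_effects optional named vector (\code{sex}, \code{pc1},
#'   \code{pc2}) of log-odds per covariate unit.
#' @param seed integer seed.
#' @export
cohort_spec <- function(n_cases, n_controls, causal_effects = numeric(),
                        intercept = 0, covariate_effects = NULL, seed = 1L) {
  stopifnot(n_cases >= 1L, n_controls >= 1L)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 causal_effects = causal_effects, intercept = intercept,
                 covariate_effects = covariate_effects,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# dosage (0/1/2) of a causal term for a diploid pair of haplotype rows
causal_dosage <- function(term, panel, dict, hap_rows) {
  if (grepl("*", term, fixed = TRUE)) {
    p <- strsplit(term, "*", fixed = TRUE)[[1]]
    labs <- panel$hla_labels[[p[1]]][[as.character(allele_resolution(p[2]))]]
    sum(labs[hap_rows] == p[2])
  } else {
    p <- strsplit(term, ":pos|:", perl = TRUE)[[1]]  # gene, pos, residue
    g <- p[1]; posn <- as.integer(p[2]); res <- p[3]
    labs <- panel$hla_labels[[g]][["4"]]
    e <- dict$entries
    carriers <- e$allele[e$gene == g & e$position == posn & e$residue == res]
    sum(labs[hap_rows] %in% carriers)
  }
}

#' Simulate a case-control cohort from a phased panel
#'
#' Individuals are formed by drawing haplotype pairs from the panel
#' (population-specific pools in two-population mode); case/control status is
#' drawn from a logistic model with additive effects of the true causal
#' dosages on the log-odds scale, and sampling continues until the requested
#' case and control counts are filled.
#'
#' @param panel labeled \code{\link{phased_panel}}.
#' @param dict \code{aa_dictionary} for residue-level causal terms.
#' @param spec a \code{\link{cohort_spec}}.
#' @param population which population pool to draw from (default
#'   \code{"pop1"}; ignored for single-population panels).
#' @return Object of class \code{hla_cohort}: classical 4-digit
#'   \code{\link{dosage_table}} (true hard-call dosages), binary
#'   \code{phenotype}, \code{covariates} matrix (sex, pc1, pc2),
#'   \code{population} label, and the sampled haplotype rows.
#' @export
simulate_cohort <- function(panel, dict, spec, population = "pop1") {
  stopifnot(inherits(spec, "cohort_spec"))
  pool <- seq_len(n_haplotypes(panel))
  pop_attr <- attr(panel, "population")
  if (!is.null(pop_attr)) {
    keep <- which(rep(pop_attr, each = 2L) == population)
    if (!length(keep)) stop("no haplotypes in population ", population)
    pool <- keep
  }
  with_seed(sub_seed(spec$seed, paste0("cohort_", population)), {
    need <- c(case = spec$n_cases, control = spec$n_controls)
    got <- c(case = 0L, control = 0L)
    max_try <- 500L * sum(need)
    rows <- matrix(0L, sum(need), 2L); pheno <- integer(sum(need))
    covs <- matrix(0, sum(need), 3L,
                   dimnames = list(NULL, c("sex", "pc1", "pc2")))
    filled <- 0L; tries <- 0L
    terms <- names(spec$causal_effects)
    while (filled < sum(need)) {
      tries <- tries + 1L
      if (tries > max_try)
        stop("could not reach requested case/control counts ",
             "(case probability too extreme)")
      hp <- sample(pool, 2L, replace = TRUE)
      cv <- c(stats::rbinom(1L, 1L, 0.5), stats::rnorm(2L))
      eta <- spec$intercept
      for (k in seq_along(terms))
        eta <- eta + spec$causal_effects[[k]] *
          causal_dosage(terms[k], panel, dict, hp)
      if (!is.null(spec$covariate_effects))
        eta <- eta + sum(spec$covariate_effects *
                           cv[names(spec$covariate_effects)])
      y <- stats::rbinom(1L, 1L, stats::plogis(eta))
      grp <- if (y == 1L) "case" else "control"
      if (got[grp] >= need[grp]) next
      got[grp] <- got[grp] + 1L; filled <- filled + 1L
      rows[filled, ] <- hp; pheno[filled] <- y; covs[filled, ] <- cv
    }
    ids <- sprintf("%s_I%05d", population, seq_len(sum(need)))
    dos <- classical_dosages_from_labels(panel, rows, ids, resolution = 4L)
    structure(list(dosages = dos, phenotype = pheno, covariates = covs,
                   population = population, sample_ids = ids,
                   hap_rows = rows),
              class = "hla_cohort")
  })
}

# hard-call classical allele dosage table from truth labels for chosen
# haplotype row pairs
classical_dosages_from_labels <- function(panel, hap_rows, ids,
                                          resolution = 4L) {
  res <- as.character(resolution)
  cols <- NULL; D <- NULL
  for (g in names(panel$hla_labels)) {
    labs <- panel$hla_labels[[g]][[res]]
    if (is.null(labs)) next
    alleles <- sort(setdiff(unique(labs), c("unknown", "inconsistent")))
    d <- sapply(alleles, function(a)
      (labs[hap_rows[, 1L]] == a) + (labs[hap_rows[, 2L]] == a))
    if (is.null(dim(d))) d <- matrix(d, nrow = nrow(hap_rows))
    D <- cbind(D, d)
    cols <- rbind(cols, data.frame(
      id = paste0(g, "*", alleles), gene = g, class = "classical_allele",
      allele = alleles, position = NA_integer_, residue = NA_character_,
      stringsAsFactors = FALSE))
  }
  rownames(D) <- ids
  dosage_table(D, cols)
}

#' @export
print.hla_cohort <- function(x, ...) {
  cat("Cohort", x$population, ":", sum(x$phenotype == 1L), "cases /",
      sum(x$phenotype == 0L), "controls;",
      ncol(x$dosages$dosages), "dosage columns\n")
  invisible(x)
}
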