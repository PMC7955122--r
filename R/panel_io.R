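#' Construct a phased haplotype panel
#'
#' A phased panel holds a haplotype-by-variant 0/1 matrix (0 = reference
#' allele, 1 = alternative allele), a position-sorted variant map, and, for a
#' reference panel, per-haplotype classical HLA allele labels at one or more
#' resolutions (2-, 4-, 6-digit).
#'
#' @param variants data.frame with columns \code{id}, \code{chrom},
#'   \code{pos_bp} (1-based), \code{ref_allele}, \code{alt_allele}.
#' @param haplotypes integer matrix of 0/1, one row per haplotype, one column
#'   per variant (same order as \code{variants}). Two adjacent rows per sample.
#' @param sample_ids character vector; haplotype rows are
#'   \code{sample_ids[1]}.1, \code{sample_ids[1]}.2, \code{sample_ids[2]}.1, ...
#' @param hla_labels nested list \code{gene -> resolution ("2","4","6") ->}
#'   character vector of per-haplotype allele names (\code{"unknown"} allowed).
#' @param gene_pos named numeric vector of representative bp positions for the
#'   HLA genes appearing in \code{hla_labels}.
#' @return An object of class \code{phased_panel}.
#' @export
phased_panel <- function(variants, haplotypes, sample_ids,
                         hla_labels = list(), gene_pos = numeric()) {
  variants <- as.data.frame(variants)
  stopifnot(all(c("id", "chrom", "pos_bp", "ref_allele", "alt_allele") %in%
                  names(variants)))
  if (anyDuplicated(variants$id))
    stop("duplicate variant ids in panel")
  if (any(variants$pos_bp < 1)) stop("variant positions must be >= 1")
  if (any(variants$ref_allele == variants$alt_allele))
    stop("ref and alt alleles must differ")
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (ncol(haplotypes) != nrow(variants))
    stop("haplotype matrix has ", ncol(haplotypes), " columns but ",
         nrow(variants), " variants")
  if (nrow(haplotypes) != 2L * length(sample_ids))
    stop("haplotype count must be twice the sample count")
  if (any(is.na(haplotypes)) || !all(haplotypes %in% c(0L, 1L)))
    stop("haplotypes must be complete 0/1")
  ord <- order(variants$pos_bp)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  haplotypes <- haplotypes[, ord, drop = FALSE]
  colnames(haplotypes) <- variants$id
  rownames(haplotypes) <- paste(rep(sample_ids, each = 2L), 1:2, sep = ".")
  for (g in names(hla_labels)) for (r in names(hla_labels[[g]]))
    if (length(hla_labels[[g]][[r]]) != nrow(haplotypes))
      stop("hla_labels[", g, "][", r, "] length != haplotype count")
  structure(list(variants = variants, haplotypes = haplotypes,
                 sample_ids = as.character(sample_ids),
                 hla_labels = hla_labels, gene_pos = gene_pos),
            class = "phased_panel")
}

#' @export
print.phased_panel <- function(x, ...) {
  cat("Phased panel:", length(x$sample_ids), "samples (",
      nrow(x$haplotypes), "haplotypes ),", nrow(x$variants), "SNVs\n")
  if (length(x$hla_labels)) {
    cat("HLA genes:", paste(names(x$hla_labels), collapse = ", "), "\n")
    res <- sort(unique(unlist(lapply(x$hla_labels, names))))
    cat("Typed resolutions:", paste(res, collapse = ", "), "digit\n")
  } else cat("No HLA labels (target panel)\n")
  invisible(x)
}

n_haplotypes <- function(panel) nrow(panel$haplotypes)

#' Read a SNP2HLA/Beagle-style phased panel
#'
#' The phased dialect has a header line \code{"I id s1 s1 s2 s2 ..."} and one
#' \code{"M <id> <a> <a> ..."} line per marker with one allele column per
#' haplotype. SNV markers carry nucleotide alleles; classical-allele markers
#' are named \code{HLA_<GENE>_<digits>} (colon-free 2/4/6-digit allele) and
#' coded \code{P}/\code{A} (present/absent). Positions and ref/alt coding come
#' from a sidecar markers file (columns: id, pos, ref, alt); HLA marker rows
#' there give each gene its representative position.
#'
#' @param path path to the \code{.bgl} file.
#' @param markers path to the markers file; defaults to \code{path} with its
#'   extension replaced by \code{.markers}.
#' @return A \code{\link{phased_panel}}; binary HLA markers are converted to
#'   allele labels and removed from the SNV matrix.
#' @export
read_beagle_phased <- function(path, markers = NULL) {
  if (is.null(markers)) markers <- sub("\\.[^.]+$", ".markers", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty beagle file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  hdr <- fields[[1]]
  if (hdr[1] != "I") stop("parse error at line 1: expected header line 'I ...'")
  haps <- hdr[-(1:2)]
  n_hap <- length(haps)
  if (n_hap < 2L || n_hap %% 2L != 0L)
    stop("parse error at line 1: haplotype columns must be even and >= 2")
  sample_ids <- haps[seq(1, n_hap, 2)]
  if (!identical(sample_ids, haps[seq(2, n_hap, 2)]))
    stop("parse error at line 1: sample ids must appear twice, adjacent")
  mk <- utils::read.table(markers, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("id", "pos", "ref", "alt"))
  rownames(mk) <- mk$id
  ids <- character(0); alle <- list()
  for (i in seq_along(fields)[-1]) {
    f <- fields[[i]]
    if (!length(f) || f[1] == "") next
    if (f[1] != "M") stop("parse error at line ", i, ": expected 'M' line")
    if (length(f) != n_hap + 2L)
      stop("parse error at line ", i, ": expected ", n_hap + 2L,
           " fields, got ", length(f))
    ids <- c(ids, f[2]); alle[[f[2]]] <- f[-(1:2)]
  }
  if (anyDuplicated(ids)) stop("duplicate marker ids in ", path)
  miss <- setdiff(ids, mk$id)
  if (length(miss)) stop("markers absent from markers file: ",
                         paste(utils::head(miss, 3), collapse = ", "))
  is_hla <- grepl("^HLA_.+_[0-9]{2}([0-9]{2}){0,2}$", ids)
  snv_ids <- ids[!is_hla]
  variants <- data.frame(id = snv_ids, chrom = "6",
                         pos_bp = mk[snv_ids, "pos"],
                         ref_allele = mk[snv_ids, "ref"],
                         alt_allele = mk[snv_ids, "alt"],
                         stringsAsFactors = FALSE)
  H <- matrix(0L, n_hap, length(snv_ids))
  for (j in seq_along(snv_ids)) {
    a <- alle[[snv_ids[j]]]
    v <- variants[j, ]
    bad <- !(a %in% c(v$ref_allele, v$alt_allele))
    if (any(bad))
      stop("parse error: marker ", v$id, " has allele '", a[which(bad)[1]],
           "' not in {", v$ref_allele, ",", v$alt_allele, "}")
    H[, j] <- as.integer(a == v$alt_allele)
  }
  # fold P/A markers into per-haplotype allele labels: a haplotype must be
  # 'P' at exactly one allele per gene and resolution; 0 or >=2 is flagged
  # "inconsistent" and resolved by exclude_inconsistent().
  hla_labels <- list(); gene_pos <- numeric(); present <- list()
  for (id in ids[is_hla]) {
    m <- regmatches(id, regexec("^HLA_(.+)_([0-9]{2}([0-9]{2}){0,2})$", id))[[1]]
    gene <- m[2]; digits <- m[3]
    a <- alle[[id]]
    if (!all(a %in% c("P", "A")))
      stop("parse error: HLA marker ", id, " must be coded P/A")
    key <- paste(gene, nchar(digits), sep = "\r")
    col <- matrix(a == "P", ncol = 1,
                  dimnames = list(NULL, allele_name_from_digits(digits)))
    present[[key]] <- cbind(present[[key]], col)
    gene_pos[gene] <- mk[id, "pos"]
  }
  for (key in names(present)) {
    gr <- strsplit(key, "\r", fixed = TRUE)[[1]]
    P <- present[[key]]
    k <- rowSums(P)
    lab <- rep("inconsistent", n_hap)
    one <- k == 1L
    lab[one] <- colnames(P)[max.col(P[one, , drop = FALSE])]
    if (is.null(hla_labels[[gr[1]]])) hla_labels[[gr[1]]] <- list()
    hla_labels[[gr[1]]][[gr[2]]] <- lab
  }
  phased_panel(variants, H, sample_ids, hla_labels, gene_pos)
}

#' Write a panel in the Beagle phased dialect
#'
#' Inverse of \code{\link{read_beagle_phased}}: writes \code{<prefix>.bgl} and
#' \code{<prefix>.markers}.
#'
#' @param panel a \code{\link{phased_panel}}.
#' @param prefix output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_beagle_phased <- function(panel, prefix) {
  bgl <- paste0(prefix, ".bgl"); mkf <- paste0(prefix, ".markers")
  n_hap <- n_haplotypes(panel)
  con <- file(bgl, "w"); on.exit(close(con))
  writeLines(paste(c("I", "id", rep(panel$sample_ids, each = 2)),
                   collapse = " "), con)
  mk <- data.frame(id = panel$variants$id, pos = panel$variants$pos_bp,
                   ref = panel$variants$ref_allele,
                   alt = panel$variants$alt_allele, stringsAsFactors = FALSE)
  for (j in seq_len(nrow(panel$variants))) {
    v <- panel$variants[j, ]
    a <- ifelse(panel$haplotypes[, j] == 1L, v$alt_allele, v$ref_allele)
    writeLines(paste(c("M", v$id, a), collapse = " "), con)
  }
  for (g in names(panel$hla_labels)) for (r in names(panel$hla_labels[[g]])) {
    labs <- panel$hla_labels[[g]][[r]]
    for (al in sort(setdiff(unique(labs), c("unknown", "inconsistent")))) {
      id <- paste0("HLA_", g, "_", allele_digits_from_name(al))
      writeLines(paste(c("M", id, ifelse(labs == al, "P", "A")),
                       collapse = " "), con)
      mk <- rbind(mk, data.frame(id = id,
                                 pos = unname(panel$gene_pos[g] %||% 0),
                                 ref = "P", alt = "A"))
    }
  }
  utils::write.table(mk, mkf, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(c(bgl, mkf))
}

#' Read a phased VCF with an optional HLA label sidecar
#'
#' Minimal reader for phased, biallelic, complete VCF (GT with \code{|}).
#' HLA truth labels, if any, come from a sidecar TSV with columns
#' sample, hap_index (1/2), gene, resolution, allele.
#'
#' @param path VCF path (uncompressed).
#' @param labels optional sidecar label TSV path.
#' @param gene_pos optional named vector of gene positions.
#' @return A \code{\link{phased_panel}}.
#' @export
read_phased_vcf <- function(path, labels = NULL, gene_pos = numeric()) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (hdr[1] != "#CHROM") stop("parse error: missing #CHROM header")
  samples <- hdr[-(1:9)]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  n <- length(rows)
  variants <- data.frame(id = character(n), chrom = character(n),
                         pos_bp = integer(n), ref_allele = character(n),
                         alt_allele = character(n), stringsAsFactors = FALSE)
  H <- matrix(0L, 2L * length(samples), n)
  for (i in seq_len(n)) {
    f <- rows[[i]]
    if (grepl(",", f[5], fixed = TRUE))
      stop("parse error at record ", i, ": multiallelic SNVs are not supported")
    variants[i, ] <- list(f[3], f[1], as.integer(f[2]), f[4], f[5])
    gt <- sub(":.*", "", f[-(1:9)])
    if (any(!grepl("^[01]\\|[01]$", gt)))
      stop("record ", i, " (", f[3], "): genotypes must be phased, complete ",
           "and biallelic; pre-phase/impute the target upstream")
    H[seq(1, by = 2, length.out = length(samples)), i] <-
      as.integer(substr(gt, 1, 1))
    H[seq(2, by = 2, length.out = length(samples)), i] <-
      as.integer(substr(gt, 3, 3))
  }
  hla_labels <- list()
  if (!is.null(labels)) {
    lab <- utils::read.table(labels, header = TRUE, sep = "\t",
                             colClasses = "character")
    lab$hap_index <- as.integer(lab$hap_index)
    for (k in seq_len(nrow(lab))) {
      g <- lab$gene[k]; r <- as.character(lab$resolution[k])
      if (is.null(hla_labels[[g]])) hla_labels[[g]] <- list()
      if (is.null(hla_labels[[g]][[r]]))
        hla_labels[[g]][[r]] <- rep("unknown", 2L * length(samples))
      row <- 2L * (match(lab$sample[k], samples) - 1L) + lab$hap_index[k]
      hla_labels[[g]][[r]][row] <- lab$allele[k]
    }
  }
  phased_panel(variants, H, samples, hla_labels, gene_pos)
}

#' Remove samples with inconsistent HLA typing
#'
#' A haplotype must carry exactly one allele per gene per typed resolution,
#' and labels must nest across resolutions (the 2-digit allele is the prefix
#' of the 4-digit allele, etc.). Samples violating either rule are removed.
#' Genes untyped for all haplotypes at a resolution have that resolution
#' dropped; genes untyped everywhere are dropped.
#'
#' @param panel a \code{\link{phased_panel}}.
#' @return The filtered panel, with attribute \code{"removed"}: a data.frame
#'   of removed sample ids and reasons.
#' @export
exclude_inconsistent <- function(panel) {
  n_hap <- n_haplotypes(panel)
  bad <- rep(FALSE, length(panel$sample_ids))
  reason <- rep(NA_character_, length(panel$sample_ids))
  flag <- function(hap_rows, why) {
    s <- unique((hap_rows + 1L) %/% 2L)
    newly <- s[!bad[s]]
    bad[newly] <<- TRUE
    reason[newly] <<- why
  }
  labs <- panel$hla_labels
  for (g in names(labs)) {
    res <- names(labs[[g]])
    for (r in res) {
      v <- labs[[g]][[r]]
      if (all(v == "unknown")) { labs[[g]][[r]] <- NULL; next }
      bad_h <- which(v == "inconsistent")
      if (length(bad_h))
        flag(bad_h, paste0(g, ": 0 or >1 present alleles at ", r, "-digit"))
    }
    res <- sort(as.integer(names(labs[[g]])))
    if (length(res) > 1) for (k in seq_len(length(res) - 1L)) {
      lo <- labs[[g]][[as.character(res[k])]]
      hi <- labs[[g]][[as.character(res[k + 1L])]]
      known <- !(lo %in% c("unknown", "inconsistent")) &
        !(hi %in% c("unknown", "inconsistent"))
      mism <- which(known & !mapply(allele_is_prefix, lo, hi))
      if (length(mism))
        flag(mism, paste0(g, ": ", res[k], "-digit label not a prefix of ",
                          res[k + 1L], "-digit label"))
    }
    if (!length(labs[[g]])) labs[[g]] <- NULL
  }
  removed <- data.frame(sample = panel$sample_ids[bad],
                        reason = reason[bad], stringsAsFactors = FALSE)
  if (!any(bad)) {
    panel$hla_labels <- labs
    attr(panel, "removed") <- removed
    return(panel)
  }
  keep_s <- !bad
  keep_h <- rep(keep_s, each = 2L)
  labs <- lapply(labs, function(by_res)
    lapply(by_res, function(v) v[keep_h]))
  out <- phased_panel(panel$variants, panel$haplotypes[keep_h, , drop = FALSE],
                      panel$sample_ids[keep_s], labs, panel$gene_pos)
  if (!length(out$sample_ids)) warning("all samples removed as inconsistent")
  attr(out, "removed") <- removed
  out
}

#' Define a gene group and its SNV window
#'
#' @param name group name.
#' @param genes ordered gene names.
#' @param gene_pos named numeric vector of representative gene positions (bp).
#' @param window_bp flanking window on each side of the gene span (default
#'   500 kb, inclusive on both ends).
#' @return An object of class \code{gene_group} with the bp \code{span}.
#' @export
gene_group <- function(name, genes, gene_pos, window_bp = 500000L) {
  stopifnot(length(genes) >= 1L, window_bp > 0)
  if (!all(genes %in% names(gene_pos)))
    stop("unknown gene name(s): ",
         paste(setdiff(genes, names(gene_pos)), collapse = ", "))
  p <- gene_pos[genes]
  structure(list(name = name, genes = genes, window_bp = window_bp,
                 span = c(max(1, min(p) - window_bp), max(p) + window_bp)),
            class = "gene_group")
}

#' Built-in representative coordinates of MHC-region genes
#'
#' Approximate GRCh37 chr6 representative positions used for grouping and
#' window construction; configurable by supplying another table.
#'
#' @return Named numeric vector of positions (bp).
#' @export
hla_gene_coords <- function() {
  path <- system.file("extdata", "hla_gene_coords.tsv", package = "hlaimpute")
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(tb$pos_bp, tb$gene)
}

# The four LD-based gene groups used for multitask training on real panels.
published_group_sets <- function() list(
  group1 = c("HLA-F", "HLA-V", "HLA-G", "HLA-H", "HLA-K", "HLA-A", "HLA-J",
             "HLA-L", "HLA-E"),
  group2 = c("HLA-C", "HLA-B", "MICA", "MICB"),
  group3 = c("HLA-DRA", "HLA-DRB9", "HLA-DRB5", "HLA-DRB4", "HLA-DRB3",
             "HLA-DRB8", "HLA-DRB7", "HLA-DRB6", "HLA-DRB2", "HLA-DRB1",
             "HLA-DQA1", "HLA-DOB", "HLA-DQB1"),
  group4 = c("TAP2", "TAP1", "HLA-DMB", "HLA-DMA", "HLA-DOA", "HLA-DPA1",
             "HLA-DPB1"))

#' Default multitask gene groups
#'
#' Returns the four LD-structure-based MHC gene groups, restricted to the
#' genes typed in the panel with at least two alleles at the requested
#' resolution. Genes not in any published group raise an error.
#'
#' @param genes character vector of gene names present in the panel.
#' @param gene_pos named position vector (default the bundled table).
#' @param n_alleles optional named integer vector of allele counts per gene;
#'   genes with fewer than 2 are excluded.
#' @param window_bp per-side window (default 500 kb).
#' @return List of \code{\link{gene_group}} objects (empty groups dropped).
#' @export
default_groups <- function(genes, gene_pos = hla_gene_coords(),
                           n_alleles = NULL, window_bp = 500000L) {
  sets <- published_group_sets()
  unknown <- setdiff(genes, unlist(sets))
  if (length(unknown))
    stop("unknown gene name(s): ", paste(unknown, collapse = ", "))
  keep <- genes
  if (!is.null(n_alleles)) keep <- genes[n_alleles[genes] >= 2L]
  out <- list()
  for (nm in names(sets)) {
    g <- intersect(sets[[nm]], keep)
    if (length(g)) out[[nm]] <- gene_group(nm, g, gene_pos, window_bp)
  }
  out
}

#' One-hot encode the SNVs of a gene-group window
#'
#' Each haplotype becomes a 2 x W binary array over the W SNVs inside the
#' group span: row 1 indicates the reference allele, row 2 the alternative;
#' every column sums to one.
#'
#' @param panel a \code{\link{phased_panel}}.
#' @param group a \code{\link{gene_group}}.
#' @return Array of dimension \code{c(2, W, n_haplotypes)} with attribute
#'   \code{"variant_ids"}.
#' @export
encode_window <- function(panel, group) {
  sel <- panel$variants$pos_bp >= group$span[1] &
    panel$variants$pos_bp <= group$span[2]
  if (!any(sel))
    stop("group '", group$name, "': no SNVs inside its window")
  encode_haplotypes(panel$haplotypes[, sel, drop = FALSE],
                    panel$variants$id[sel])
}

# one-hot encoding of a 0/1 haplotype matrix -> (2, W, H) array
encode_haplotypes <- function(hapmat, variant_ids = colnames(hapmat)) {
  H <- nrow(hapmat); W <- ncol(hapmat)
  x <- array(0, dim = c(2L, W, H))
  alt <- t(hapmat)                       # W x H
  x[1L, , ] <- 1 - alt
  x[2L, , ] <- alt
  attr(x, "variant_ids") <- variant_ids
  x
}

#' Read an amino-acid dictionary
#'
#' TSV with columns gene, allele (4-digit), position, residue
#' (single letter, or \code{"absent"} when the protein lacks the position).
#'
#' @param path TSV path.
#' @return Object of class \code{aa_dictionary}: a data.frame plus an index.
#' @export
read_aa_dictionary <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "allele", "position", "residue") %in% names(tb)))
  aa_dictionary(tb)
}

#' @rdname read_aa_dictionary
#' @param entries data.frame with columns gene, allele, position, residue.
#' @export
aa_dictionary <- function(entries) {
  entries <- as.data.frame(entries)
  key <- paste(entries$gene, entries$allele, entries$position)
  if (anyDuplicated(key))
    stop("amino-acid dictionary maps one (gene, allele, position) twice")
  structure(list(entries = entries), class = "aa_dictionary")
}

#' @export
print.aa_dictionary <- function(x, ...) {
  cat("Amino-acid dictionary:", length(unique(x$entries$gene)), "gene(s),",
      length(unique(paste(x$entries$gene, x$entries$allele))), "alleles,",
      length(unique(paste(x$entries$gene, x$entries$position))),
      "positions\n")
  invisible(x)
}

#' Write an amino-acid dictionary TSV
#' @param dict an \code{aa_dictionary}.
#' @param path output path.
#' @export
write_aa_dictionary <- function(dict, path) {
  utils::write.table(dict$entries, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' Write a dosage table
#'
#' @param table a \code{\link{dosage_table}}.
#' @param path output path.
#' @param format \code{"tsv"} (one row per variant/allele, one column per
#'   sample, 4 decimals) or \code{"vcf_ds"} (VCF with a DS FORMAT field).
#' @export
write_dosages <- function(table, path, format = c("tsv", "vcf_ds")) {
  format <- match.arg(format)
  D <- table$dosages; info <- table$info
  if (format == "tsv") {
    hdr <- paste(c("id", "gene", "class", rownames(D)), collapse = "\t")
    body <- vapply(seq_len(ncol(D)), function(j)
      paste(c(info$id[j], info$gene[j], info$class[j],
              formatC(D[, j], digits = 4, format = "f")), collapse = "\t"),
      "")
    writeLines(c(hdr, body), path)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT", rownames(D)), collapse = "\t")), con)
    for (j in seq_len(ncol(D)))
      writeLines(paste(c("6", info$pos_bp[j] %||% 0, info$id[j], "P", "A",
                         ".", ".", ".", "DS",
                         formatC(D[, j], digits = 4, format = "f")),
                       collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a dosage TSV written by \code{\link{write_dosages}}
#' @param path TSV path.
#' @return A \code{\link{dosage_table}}.
#' @export
read_dosages <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  info <- df[, 1:3, drop = FALSE]
  D <- t(as.matrix(df[, -(1:3), drop = FALSE]))
  if (nrow(info)) colnames(D) <- info$id
  dosage_table(D, info)
}

#' Construct a dosage table
#'
#' Per-individual allelic dosages in [0, 2]. Columns are variants/alleles,
#' rows are individuals.
#'
#' @param dosages numeric matrix, individuals x columns.
#' @param info data.frame describing the columns: \code{id}, \code{gene},
#'   \code{class} (one of classical_allele, residue_binary,
#'   position_multiallelic, snv) and optional \code{allele},
#'   \code{position}, \code{residue}.
#' @return Object of class \code{dosage_table}.
#' @export
dosage_table <- function(dosages, info) {
  dosages <- as.matrix(dosages)
  info <- as.data.frame(info)
  stopifnot(ncol(dosages) == nrow(info),
            all(c("id", "gene", "class") %in% names(info)))
  if (ncol(dosages)) colnames(dosages) <- info$id
  structure(list(dosages = dosages, info = info), class = "dosage_table")
}

#' @export
print.dosage_table <- function(x, ...) {
  cat("Dosage table:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "columns (",
      paste(names(table(x$info$class)), table(x$info$class),
            collapse = ", "), ")\n")
  invisible(x)
}
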