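test_that("beagle phased dialect reads SNVs and folds HLA markers to labels", {
  dir <- withr::local_tempdir()
  panel <- read_beagle_phased(write_toy_beagle(dir))
  expect_s3_class(panel, "phased_panel")
  expect_equal(nrow(panel$haplotypes), 4L)
  expect_equal(nrow(panel$variants), 3L)
  expect_equal(panel$sample_ids, c("s1", "s2"))
  # rs1: alleles A G A A with ref A alt G
  expect_equal(unname(panel$haplotypes[, "rs1"]), c(0L, 1L, 0L, 0L))
  expect_equal(panel$hla_labels$A$`2`, c("01", "02", "01", "02"))
  expect_equal(unname(panel$gene_pos["A"]), 250)
})

test_that("a haplotype present at two alleles of one gene is flagged and its
           sample removed", {
  dir <- withr::local_tempdir()
  bgl <- write_toy_beagle(dir, list(`01` = c("P", "A", "P", "A"),
                                    `02` = c("P", "P", "A", "P")))
  panel <- read_beagle_phased(bgl)
  expect_equal(panel$hla_labels$A$`2`[1], "inconsistent")
  out <- exclude_inconsistent(panel)
  rem <- attr(out, "removed")
  expect_equal(rem$sample, "s1")
  expect_equal(out$sample_ids, "s2")
  expect_equal(out$hla_labels$A$`2`, c("01", "02"))
})

test_that("zero present alleles at a typed gene is also inconsistent", {
  dir <- withr::local_tempdir()
  bgl <- write_toy_beagle(dir, list(`01` = c("P", "A", "A", "A"),
                                    `02` = c("A", "P", "A", "P")))
  panel <- read_beagle_phased(bgl)
  out <- exclude_inconsistent(panel)
  expect_equal(attr(out, "removed")$sample, "s2")
})

test_that("cross-resolution prefix violations remove the sample", {
  sim <- noiseless_sim(20L)
  panel <- sim$panel
  # sample 1, haplotype 1: 2-digit label contradicts the 4-digit label
  l4 <- panel$hla_labels$G1$`4`[1]
  panel$hla_labels$G1$`2`[1] <-
    setdiff(unique(panel$hla_labels$G1$`2`), substr(l4, 1, 2))[1]
  out <- exclude_inconsistent(panel)
  expect_equal(attr(out, "removed")$sample, panel$sample_ids[1])
  expect_match(attr(out, "removed")$reason, "prefix")
  expect_equal(length(out$sample_ids), length(panel$sample_ids) - 1L)
})

test_that("a gene untyped for all samples is dropped without removals", {
  sim <- noiseless_sim(20L)
  panel <- sim$panel
  panel$hla_labels$G2$`2`[] <- "unknown"
  panel$hla_labels$G2$`4`[] <- "unknown"
  out <- exclude_inconsistent(panel)
  expect_equal(nrow(attr(out, "removed")), 0L)
  expect_false("G2" %in% names(out$hla_labels))
  expect_equal(length(out$sample_ids), length(panel$sample_ids))
})

test_that("write -> read round trip reproduces matrices and labels", {
  sim <- noiseless_sim(30L)
  dir <- withr::local_tempdir()
  write_beagle_phased(sim$panel, file.path(dir, "rt"))
  back <- read_beagle_phased(file.path(dir, "rt.bgl"))
  expect_equal(unname(back$haplotypes), unname(sim$panel$haplotypes))
  expect_equal(back$variants$pos_bp, sim$panel$variants$pos_bp)
  for (g in names(sim$panel$hla_labels))
    for (r in names(sim$panel$hla_labels[[g]]))
      expect_equal(back$hla_labels[[g]][[r]], sim$panel$hla_labels[[g]][[r]])
})

test_that("parse errors name the offending construct", {
  dir <- withr::local_tempdir()
  bgl <- file.path(dir, "bad.bgl")
  writeLines(c("I id s1 s1", "M rs1 A G C"), bgl)
  writeLines("rs1\t100\tA\tG", file.path(dir, "bad.markers"))
  expect_error(read_beagle_phased(bgl), "line 2")
})

test_that("one-hot window encoding has unit column sums and honours the span", {
  sim <- noiseless_sim(20L)
  gr <- sim$groups[[1]]
  X <- encode_window(sim$panel, gr)
  expect_equal(dim(X)[1], 2L)
  expect_true(all(X[1, , ] + X[2, , ] == 1))
  W_expected <- sum(sim$panel$variants$pos_bp >= gr$span[1] &
                      sim$panel$variants$pos_bp <= gr$span[2])
  expect_equal(dim(X)[2], W_expected)
  # hand-built three-SNV haplotype [0,1,0]
  toy <- phased_panel(
    data.frame(id = c("v1", "v2", "v3"), chrom = "6",
               pos_bp = c(10L, 20L, 30L), ref_allele = "A",
               alt_allele = "G"),
    matrix(c(0L, 1L, 0L, 1L, 1L, 1L), 2, byrow = TRUE), c("s1"),
    gene_pos = c(G = 20))
  Xt <- encode_window(toy, gene_group("g", "G", c(G = 20), 15L))
  expect_equal(Xt[, , 1], matrix(c(1, 0, 0, 1, 1, 0), 2))
  # all-alt haplotype: alt row is all ones
  expect_equal(unname(Xt[2, , 2]), c(1, 1, 1))
  # narrower window drops the first SNV
  Xn <- encode_window(toy, gene_group("g", "G", c(G = 25), 6L))
  expect_equal(dim(Xn)[2], 2L)
  expect_error(encode_window(toy, gene_group("g", "G", c(G = 500), 5L)),
               "no SNVs")
})

test_that("phased VCF reader enforces phased biallelic completeness", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "t.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "s1", "s2", sep = "\t"),
               paste("6", "100", "rs1", "A", "G", ".", ".", ".", "GT",
                     "0|1", "1|1", sep = "\t"),
               paste("6", "200", "rs2", "C", "T", ".", ".", ".", "GT",
                     "0|0", "1|0", sep = "\t")), vcf)
  lab <- file.path(dir, "lab.tsv")
  writeLines(c("sample\thap_index\tgene\tresolution\tallele",
               "s1\t1\tA\t2\t01", "s1\t2\tA\t2\t02",
               "s2\t1\tA\t2\t01", "s2\t2\tA\t2\t01"), lab)
  panel <- read_phased_vcf(vcf, lab, gene_pos = c(A = 150))
  expect_equal(unname(panel$haplotypes[, "rs1"]), c(0L, 1L, 1L, 1L))
  expect_equal(panel$hla_labels$A$`2`, c("01", "02", "01", "01"))
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "s1", sep = "\t"),
               paste("6", "100", "rs1", "A", "G,T", ".", ".", ".", "GT",
                     "0|1", sep = "\t")), vcf)
  expect_error(read_phased_vcf(vcf), "multiallelic")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "s1", sep = "\t"),
               paste("6", "100", "rs1", "A", "G", ".", ".", ".", "GT",
                     "0/1", sep = "\t")), vcf)
  expect_error(read_phased_vcf(vcf), "phased")
})

test_that("dosage TSV writing round-trips to 1e-4 and handles empty tables", {
  pr <- random_probs(5, 3)
  dt <- diploid_dosage(pr)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "d.tsv")
  write_dosages(dt, path)
  back <- read_dosages(path)
  expect_equal(unname(back$dosages), unname(dt$dosages), tolerance = 1e-4)
  expect_equal(back$info$id, dt$info$id)
  # a hard dosage of 2 is printed with 4 decimals
  hard <- dosage_table(matrix(2, 1, 1, dimnames = list("s", NULL)),
                       data.frame(id = "G1*a1", gene = "G1",
                                  class = "classical_allele"))
  write_dosages(hard, path)
  expect_match(readLines(path)[2], "2.0000", fixed = TRUE)
  empty <- dosage_table(matrix(numeric(0), 2, 0,
                               dimnames = list(c("s1", "s2"), NULL)),
                        data.frame(id = character(0), gene = character(0),
                                   class = character(0)))
  write_dosages(empty, path)
  expect_equal(length(readLines(path)), 1L)
})

test_that("default groups restrict the published sets to available genes", {
  gp <- hla_gene_coords()
  grs <- default_groups(c("HLA-C", "HLA-B", "MICA", "MICB"), gp)
  expect_equal(grs$group2$genes, c("HLA-C", "HLA-B", "MICA", "MICB"))
  grs2 <- default_groups(c("HLA-C", "HLA-B"), gp)
  expect_equal(grs2$group2$genes, c("HLA-C", "HLA-B"))
  # allele-count restriction drops single-allele genes
  grs3 <- default_groups(c("HLA-C", "HLA-B", "MICA"), gp,
                         n_alleles = c(`HLA-C` = 10L, `HLA-B` = 20L,
                                       MICA = 1L))
  expect_equal(grs3$group2$genes, c("HLA-C", "HLA-B"))
  expect_error(default_groups(c("HLA-C", "NOTAGENE"), gp), "unknown gene")
  expect_equal(length(default_groups("HLA-A", gp)), 1L)
})

test_that("panel constructor rejects malformed input", {
  v <- data.frame(id = "v1", chrom = "6", pos_bp = 1L, ref_allele = "A",
                  alt_allele = "A")
  expect_error(phased_panel(v, matrix(0L, 2, 1), "s1"), "differ")
  v$alt_allele <- "G"
  expect_error(phased_panel(v, matrix(0L, 3, 1), c("s1", "s2")), "twice")
  expect_error(phased_panel(v, matrix(2L, 2, 1), "s1"), "0/1")
})
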