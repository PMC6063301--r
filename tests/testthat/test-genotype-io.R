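test_that("hand-encoded bed file decodes to the expected dosage matrix", {
  tmp <- withr::local_tempdir()
  # 3 samples x 2 variants: s1=(0,1), s2=(2,NA), s3=(1,0)
  # variant 1 codes (low bits first): 00 hom-A1, 11 hom-A2, 10 het -> 0x2C
  # variant 2 codes: 10 het, 01 missing, 00 hom-A1 -> 0x06
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x2c, 0x06)),
           file.path(tmp, "t.bed"))
  writeLines(c("1\tv1\t0\t100\tA\tG", "1\tv2\t0\t200\tA\tG"),
             file.path(tmp, "t.bim"))
  writeLines(c("F1\ts1\t0\t0\t0\t-9", "F1\ts2\t0\t0\t0\t-9",
               "F2\ts3\t0\t0\t0\t-9"), file.path(tmp, "t.fam"))
  p <- read_plink(file.path(tmp, "t.bed"))
  expect_equal(unname(p$genotypes),
               matrix(c(0L, 2L, 1L, 1L, NA, 0L), nrow = 3))
  expect_equal(p$variants$vid, c("v1", "v2"))
  expect_equal(p$samples$sample_id, c("s1", "s2", "s3"))
  expect_equal(p$samples$population, c("F1", "F1", "F2"))
})

test_that("bed reader rejects bad magic and truncation, allows 0 variants", {
  tmp <- withr::local_tempdir()
  writeLines(character(0), file.path(tmp, "t.bim"))
  writeLines("F1\ts1\t0\t0\t0\t-9", file.path(tmp, "t.fam"))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), file.path(tmp, "t.bed"))
  p <- read_plink(file.path(tmp, "t.bed"))
  expect_equal(n_variants(p), 0L)

  writeBin(as.raw(c(0x00, 0x1b, 0x01)), file.path(tmp, "bad.bed"))
  file.copy(file.path(tmp, "t.bim"), file.path(tmp, "bad.bim"))
  file.copy(file.path(tmp, "t.fam"), file.path(tmp, "bad.fam"))
  expect_error(read_plink(file.path(tmp, "bad.bed")), "magic")

  writeLines("1\tv1\t0\t100\tA\tG", file.path(tmp, "tr.bim"))
  file.copy(file.path(tmp, "t.fam"), file.path(tmp, "tr.fam"))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), file.path(tmp, "tr.bed"))
  expect_error(read_plink(file.path(tmp, "tr.bed")), "truncated")
})

test_that("PLINK round-trip is bit-exact including missingness", {
  withr::local_seed(7)
  g <- matrix(sample(c(0:2, NA), 35 * 41, replace = TRUE), nrow = 35)
  p <- make_panel(g, chrom = rep(c("1", "2"), c(20, 21)))
  tmp <- withr::local_tempdir()
  write_plink(p, file.path(tmp, "rt"))
  p2 <- read_plink(file.path(tmp, "rt.bed"))
  expect_identical(unname(p2$genotypes), unname(p$genotypes))
  expect_equal(p2$variants$pos, p$variants$pos)
  expect_equal(p2$variants$allele_a, p$variants$allele_a)
})

test_that("VCF parsing follows the dosage-only GT contract", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\tv2\tC\tT\t.\tPASS\t.\tGT\t0|1\t./.\t1|1",
    "1\t300\tv3\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/0\t0/0"
  ), tmp)
  expect_warning(p <- read_vcf(tmp), "skipped 1")
  expect_equal(n_variants(p), 2L)
  expect_equal(unname(p$genotypes[, 1]), c(0L, 1L, 2L))
  # phase ignored, missing propagated
  expect_equal(unname(p$genotypes[, 2]), c(1L, NA, 2L))
  expect_equal(p$variants$allele_a, c("A", "C"))
  expect_equal(p$variants$allele_b, c("G", "T"))
})

test_that("VCF round-trip is bit-exact", {
  withr::local_seed(11)
  g <- matrix(sample(c(0:2, NA), 9 * 25, replace = TRUE), nrow = 9)
  p <- make_panel(g)
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(p, tmp)
  p2 <- read_vcf(tmp)
  expect_identical(unname(p2$genotypes), unname(p$genotypes))
})

test_that("metadata aggregation, altitude conflicts and coverage checks", {
  tab <- tibble::tibble(
    sample_id = c("a1", "a2", "b1", "b2"),
    population = c("AAA", "AAA", "BBB", "BBB"),
    altitude_m = c(3000, 3000, 150, 150)
  )
  pp <- population_panel(tab)
  expect_equal(nrow(pp), 2L)
  expect_equal(pp$n_samples, c(2L, 2L))
  # the 2,500 m rule: >= is high altitude
  expect_equal(pp$high_altitude[pp$code == "AAA"], TRUE)
  expect_equal(pp$high_altitude[pp$code == "BBB"], FALSE)
  expect_true(population_panel(
    tibble::tibble(sample_id = "x", population = "CCC",
                   altitude_m = 2500))$high_altitude)

  tab$altitude_m[2] <- 2999
  expect_error(population_panel(tab), "conflicting")

  tmp <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(
    tibble::tibble(sample_id = "s1", population = "AAA",
                   altitude_m = 3000),
    tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  panel <- make_panel(matrix(c(0L, 1L), nrow = 2), pops = "AAA")
  expect_error(read_metadata(tmp, panel), "s2")
})

test_that("merge intersects variants and reconciles swapped alleles", {
  g1 <- matrix(c(0L, 1L, 2L,  2L, 2L, 0L,  1L, 1L, 1L), nrow = 3)
  p1 <- make_panel(g1, pos = c(100, 200, 300))
  # panel2 shares pos 100 and 300 only; pos 100 has swapped alleles
  g2 <- matrix(c(2L, 0L,  0L, 2L), nrow = 2)
  v2 <- tibble::tibble(chrom = "1", pos = c(100L, 300L),
                       vid = c("w1", "w3"),
                       allele_a = c("G", "A"), allele_b = c("A", "G"),
                       ancestral = "unknown")
  s2 <- tibble::tibble(sample_id = c("t1", "t2"), population = "POP2")
  p2 <- genotype_panel(g2, v2, s2)
  m <- merge_panels(p1, p2)
  expect_equal(n_variants(m), 2L)
  expect_equal(n_samples(m), 5L)
  # swapped variant recoded 2 - g: panel2 column (2,0) -> (0,2)
  expect_equal(unname(m$genotypes[4:5, 1]), c(0L, 2L))
  # allele frequencies invariant under the swap
  f1 <- mean(p2$genotypes[, 1]) / 2           # freq of panel2 allele_b = A
  f_merged <- mean(m$genotypes[4:5, 1]) / 2   # freq of allele_b = G
  expect_equal(f_merged, 1 - f1)
})

test_that("merge drops strand-ambiguous SNPs and rejects duplicate samples", {
  v1 <- tibble::tibble(chrom = "1", pos = c(100L, 200L),
                       vid = c("v1", "v2"),
                       allele_a = c("A", "C"), allele_b = c("T", "G"),
                       ancestral = "unknown")
  p1 <- genotype_panel(matrix(c(0L, 1L, 1L, 2L), nrow = 2), v1,
                       tibble::tibble(sample_id = c("s1", "s2"),
                                      population = "P"))
  p2 <- genotype_panel(matrix(c(0L, 1L, 1L, 2L), nrow = 2), v1,
                       tibble::tibble(sample_id = c("u1", "u2"),
                                      population = "Q"))
  expect_message(m <- merge_panels(p1, p2), "strand-ambiguous")
  expect_equal(n_variants(m), 0L)  # A/T and C/G both dropped

  p2dup <- genotype_panel(matrix(c(0L, 1L, 1L, 2L), nrow = 2), v1,
                          tibble::tibble(sample_id = c("s1", "u2"),
                                         population = "Q"))
  expect_error(merge_panels(p1, p2dup), "duplicate")
})
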