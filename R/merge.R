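DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_strand_ambiguous <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Merge two genotype panels on shared variants
#'
#' Intersects variants on `(chrom, pos)` and concatenates samples. Alleles
#' are reconciled against the first panel: same-orientation variants pass
#' through, REF/ALT swaps recode the second panel's dosages as `2 - g`, and
#' strand flips (allele complements, with or without a swap) are resolved.
#' A/T and C/G SNPs are always dropped as strand-ambiguous, and variants
#' whose alleles cannot be reconciled are dropped with a message.
#'
#' @param panel1,panel2 [genotype_panel()] objects.
#' @return a merged [genotype_panel()]; variant metadata (ids, ancestral
#'   annotation, cm) is taken from `panel1`.
#' @export
merge_panels <- function(panel1, panel2) {
  dup <- intersect(panel1$samples$sample_id, panel2$samples$sample_id)
  if (length(dup)) {
    abort(paste("duplicate sample id(s) across panels:",
                paste(dup, collapse = ", ")))
  }
  k1 <- paste(panel1$variants$chrom, panel1$variants$pos)
  k2 <- paste(panel2$variants$chrom, panel2$variants$pos)
  i1 <- which(k1 %in% k2)
  i2 <- match(k1[i1], k2)

  a1 <- panel1$variants$allele_a[i1]; b1 <- panel1$variants$allele_b[i1]
  a2 <- panel2$variants$allele_a[i2]; b2 <- panel2$variants$allele_b[i2]
  amb <- is_strand_ambiguous(a1, b1) | is_strand_ambiguous(a2, b2)
  same <- a1 == a2 & b1 == b2
  swap <- a1 == b2 & b1 == a2
  flip <- DNA_COMPLEMENT[a2] == a1 & DNA_COMPLEMENT[b2] == b1
  flip_swap <- DNA_COMPLEMENT[b2] == a1 & DNA_COMPLEMENT[a2] == b1

  usable <- !amb & (same | swap | flip | flip_swap)
  n_amb <- sum(amb)
  n_bad <- sum(!amb & !usable)
  if (n_amb) inform(sprintf("dropped %d strand-ambiguous (A/T or C/G) SNP(s)",
                            n_amb))
  if (n_bad) inform(sprintf("dropped %d SNP(s) with irreconcilable alleles",
                            n_bad))
  i1 <- i1[usable]; i2 <- i2[usable]
  recode <- (swap | flip_swap)[usable]

  g2 <- panel2$genotypes[, i2, drop = FALSE]
  if (any(recode)) {
    g2[, recode] <- 2L - g2[, recode, drop = FALSE]
  }
  geno <- rbind(panel1$genotypes[, i1, drop = FALSE], g2)
  genotype_panel(geno,
                 panel1$variants[i1, , drop = FALSE],
                 dplyr::bind_rows(panel1$samples, panel2$samples))
}
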