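# PLINK 1 binary codec. bed is SNP-major: per variant, ceiling(n/4) bytes,
# each byte holding 4 samples from the low-order bit pair upward.
# 2-bit codes: 00 hom A1, 01 missing, 10 het, 11 hom A2.
# Dosages count the A2 allele (allele_b), so 00->0, 10->1, 11->2, 01->NA.

BED_MAGIC <- as.raw(c(0x6c, 0x1b))
BED_SNP_MAJOR <- as.raw(0x01)

# 256 x 4 lookup: decoded dosages of the 4 bit pairs of each byte value
bed_decode_table <- local({
  tab <- matrix(NA_integer_, 256L, 4L)
  code_map <- c(`0` = 0L, `1` = NA_integer_, `2` = 1L, `3` = 2L)
  for (b in 0:255) {
    for (k in 1:4) {
      code <- bitwAnd(bitwShiftR(b, 2L * (k - 1L)), 3L)
      tab[b + 1L, k] <- code_map[[as.character(code)]]
    }
  }
  tab
})

#' Read a PLINK 1 binary fileset
#'
#' Reads `.bed`/`.bim`/`.fam` into a [genotype_panel()]. The bed file must be
#' in SNP-major mode (the PLINK 1 default). Dosages count the A2 allele
#' (`allele_b`); variant order follows the bim file, sample order the fam
#' file. The fam family id is taken as the population code.
#'
#' @param bed_path,bim_path,fam_path file paths; `bim_path`/`fam_path`
#'   default to `bed_path` with the extension swapped.
#' @return a [genotype_panel()].
#' @export
read_plink <- function(bed_path,
                       bim_path = sub("\\.bed$", ".bim", bed_path),
                       fam_path = sub("\\.bed$", ".fam", bed_path)) {
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) abort(paste("file not found:", p))
  }
  bim <- utils::read.table(bim_path, header = FALSE, colClasses = c(
    "character", "character", "numeric", "integer", "character", "character"
  ), col.names = c("chrom", "vid", "cm", "pos", "a1", "a2"))
  fam <- utils::read.table(fam_path, header = FALSE,
                           colClasses = "character",
                           col.names = c("fid", "iid", "pat", "mat",
                                         "sex", "pheno"))
  n <- nrow(fam)
  m <- nrow(bim)
  bpv <- ceiling(n / 4)

  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != BED_MAGIC[1] || raw[2] != BED_MAGIC[2]) {
    abort(sprintf(
      "not a PLINK bed file: bad magic bytes at offset 0 (got 0x%s 0x%s)",
      if (length(raw) >= 1) format(raw[1]) else "??",
      if (length(raw) >= 2) format(raw[2]) else "??"))
  }
  if (raw[3] != BED_SNP_MAJOR) {
    abort(sprintf("bed file at offset 2 is 0x%s: only SNP-major mode (0x01) is supported",
                  format(raw[3])))
  }
  body <- raw[-(1:3)]
  if (length(body) != bpv * m) {
    abort(sprintf(
      "truncated bed file: expected %d data bytes after offset 3, found %d",
      bpv * m, length(body)))
  }
  geno <- matrix(NA_integer_, nrow = n, ncol = m)
  if (m > 0 && n > 0) {
    bytes <- matrix(as.integer(body), nrow = bpv, ncol = m)
    for (k in 1:4) {
      rows <- seq.int(k, by = 4L, length.out = bpv)
      rows <- rows[rows <= n]
      if (!length(rows)) next
      byte_rows <- (rows - k) %/% 4L + 1L
      geno[rows, ] <- bed_decode_table[bytes[byte_rows, , drop = FALSE] + 1L, k]
    }
  }
  variants <- tibble::tibble(
    chrom = sub("^chr", "", bim$chrom), pos = bim$pos, vid = bim$vid,
    allele_a = bim$a1, allele_b = bim$a2,
    ancestral = "unknown", cm = bim$cm
  )
  samples <- tibble::tibble(sample_id = fam$iid, population = fam$fid)
  genotype_panel(geno, variants, samples)
}

#' Write a genotype panel as a PLINK 1 binary fileset
#'
#' Inverse of [read_plink()]: writes `.bed` (SNP-major), `.bim` and `.fam`
#' files. Round-trips the dosage matrix bit-exactly, including missingness.
#'
#' @param panel a [genotype_panel()].
#' @param prefix output path prefix; files `<prefix>.bed/.bim/.fam` are
#'   created.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  n <- n_samples(panel)
  m <- n_variants(panel)
  bpv <- ceiling(n / 4)
  cm <- panel$variants[["cm"]] %||% rep(0, m)
  cm[is.na(cm)] <- 0
  bim <- data.frame(panel$variants$chrom, panel$variants$vid, cm,
                    panel$variants$pos, panel$variants$allele_a,
                    panel$variants$allele_b)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(panel$samples$population, panel$samples$sample_id,
                    0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  # dosage -> 2-bit code: 0->00, 1->10, 2->11, NA->01
  code_of <- c(0L, 2L, 3L)
  g <- panel$genotypes
  codes <- matrix(1L, nrow = n, ncol = m)
  ok <- !is.na(g)
  codes[ok] <- code_of[g[ok] + 1L]
  # pad to a multiple of 4 samples with code 00 (ignored on read)
  if (n %% 4 != 0) {
    codes <- rbind(codes, matrix(0L, nrow = 4 - n %% 4, ncol = m))
  }
  shifted <- codes * c(1L, 4L, 16L, 64L)  # recycles cleanly: nrow %% 4 == 0
  dim(shifted) <- c(4L, bpv * m)
  bytes <- as.raw(colSums(shifted))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(BED_MAGIC, BED_SNP_MAJOR, bytes), con)
  invisible(prefix)
}
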