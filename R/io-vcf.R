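#' Read genotypes from a VCF file
#'
#' Parses the GT field of a VCF (v4.x, plain text) into a
#' [genotype_panel()]. Only biallelic SNP records are kept; multi-allelic or
#' non-SNP records are skipped with a warning giving the count. Phase is
#' ignored: dosage is the count of ALT alleles, and any genotype containing
#' a missing allele (`.`) becomes `NA`. REF is stored as `allele_a`, ALT as
#' `allele_b`.
#'
#' @param vcf_path path to an uncompressed VCF file.
#' @param populations optional named character vector mapping sample id to
#'   population code; unmatched samples get population `"NA"`.
#' @return a [genotype_panel()].
#' @export
read_vcf <- function(vcf_path, populations = NULL) {
  lines <- readLines(vcf_path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) abort("no #CHROM header line in VCF")
  header <- strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 10) abort("VCF has no sample columns")
  sample_ids <- header[-(1:9)]
  body <- lines[-seq_len(hdr[1])]
  body <- body[nzchar(body)]

  fields <- strsplit(body, "\t", fixed = TRUE)
  chrom <- vapply(fields, `[[`, "", 1L)
  pos <- as.integer(vapply(fields, `[[`, "", 2L))
  vid <- vapply(fields, `[[`, "", 3L)
  ref <- vapply(fields, `[[`, "", 4L)
  alt <- vapply(fields, `[[`, "", 5L)
  fmt <- vapply(fields, `[[`, "", 9L)

  keep <- nchar(ref) == 1L & nchar(alt) == 1L & alt != "." &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!keep)) {
    warn(sprintf("skipped %d non-biallelic-SNP record(s)", sum(!keep)))
  }
  fields <- fields[keep]
  chrom <- chrom[keep]; pos <- pos[keep]; vid <- vid[keep]
  ref <- ref[keep]; alt <- alt[keep]
  has_gt <- vapply(strsplit(fmt[keep], ":", fixed = TRUE),
                   function(f) match("GT", f, nomatch = 0L), 0L)
  if (any(has_gt == 0L)) abort("VCF record without GT in FORMAT")

  m <- length(fields)
  n <- length(sample_ids)
  geno <- matrix(NA_integer_, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    gt <- vapply(strsplit(fields[[j]][-(1:9)], ":", fixed = TRUE),
                 `[[`, "", has_gt[j])
    alleles <- strsplit(gt, "[/|]")
    geno[, j] <- vapply(alleles, function(a) {
      if (any(a == ".")) NA_integer_ else sum(a == "1")
    }, 0L)
  }
  auto_vid <- vid == "."
  vid[auto_vid] <- paste0(chrom[auto_vid], ":", pos[auto_vid])
  variants <- tibble::tibble(
    chrom = sub("^chr", "", chrom), pos = pos, vid = vid,
    allele_a = ref, allele_b = alt, ancestral = "unknown"
  )
  pop <- if (is.null(populations)) rep("NA", n) else {
    unname(populations[sample_ids])
  }
  pop[is.na(pop)] <- "NA"
  samples <- tibble::tibble(sample_id = sample_ids, population = pop)
  genotype_panel(geno, variants, samples)
}

#' Write a genotype panel as VCF
#'
#' Emits a minimal VCF v4.2 with GT-only genotypes (unphased). Round-trips
#' the dosage matrix bit-exactly through [read_vcf()].
#'
#' @param panel a [genotype_panel()].
#' @param vcf_path output path.
#' @return `vcf_path`, invisibly.
#' @export
write_vcf <- function(panel, vcf_path) {
  gt_of <- c("0/0", "0/1", "1/1")
  g <- panel$genotypes
  gt <- matrix("./.", nrow = nrow(g), ncol = ncol(g))
  ok <- !is.na(g)
  gt[ok] <- gt_of[g[ok] + 1L]
  v <- panel$variants
  recs <- paste(v$chrom, v$pos, v$vid, v$allele_a, v$allele_b,
                ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  if (n_variants(panel) == 0) recs <- character(0)
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples$sample_id), collapse = "\t"),
    recs
  ), vcf_path)
  invisible(vcf_path)
}
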