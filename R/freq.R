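#' Per-population derived allele frequencies
#'
#' Counts derived alleles per variant and population. The derived allele is
#' resolved from the variant's `ancestral` annotation: when `allele_a` is
#' ancestral the derived frequency is the `allele_b` dosage frequency, when
#' `allele_b` is ancestral it is the complement, and variants with unknown
#' polarization get `NA` frequency in polarized mode (and are flagged).
#' Frequencies are `count / (2 x genotyped samples)`; populations with no
#' genotyped sample at a variant get a missing entry.
#'
#' @param panel a [genotype_panel()].
#' @param populations character vector of population codes (default: all in
#'   the panel).
#' @param polarized if `TRUE` (default) report derived-allele frequencies;
#'   if `FALSE`, report `allele_b` frequencies regardless of annotation.
#' @return tibble with columns `vid`, `chrom`, `pos`, `pop`, `count`,
#'   `total`, `freq`, `polarized_ok`.
#' @export
allele_frequencies <- function(panel, populations = NULL, polarized = TRUE) {
  pops <- populations %||% unique(panel$samples$population)
  if (!length(pops)) abort("no populations given")
  keep <- panel$samples$population %in% pops
  g <- panel$genotypes[keep, , drop = FALSE]
  grp <- factor(panel$samples$population[keep], levels = pops)
  counts <- rowsum(replace(g, is.na(g), 0L), grp)       # derived-b counts
  totals <- rowsum((!is.na(g)) * 2L, grp)
  freq_b <- ifelse(totals > 0, counts / totals, NA_real_)

  anc <- panel$variants$ancestral
  ok <- anc %in% c("a", "b")
  if (polarized) {
    flip <- matrix(anc == "b", nrow = nrow(freq_b), ncol = ncol(freq_b),
                   byrow = TRUE)
    freq <- ifelse(flip, 1 - freq_b, freq_b)
    count <- ifelse(flip, totals - counts, counts)
    freq[, !ok] <- NA_real_
  } else {
    freq <- freq_b
    count <- counts
  }
  tibble::tibble(
    vid = rep(panel$variants$vid, each = length(pops)),
    chrom = rep(panel$variants$chrom, each = length(pops)),
    pos = rep(panel$variants$pos, each = length(pops)),
    pop = rep(pops, times = n_variants(panel)),
    count = as.vector(count),
    total = as.vector(totals),
    freq = as.vector(freq),
    polarized_ok = rep(if (polarized) ok else TRUE,
                       each = length(pops))
  )
}

#' Pivot a frequency table to a population x variant matrix
#'
#' @param freq_table output of [allele_frequencies()].
#' @return numeric matrix, rows = populations, columns = variants (in first
#'   appearance order).
#' @export
freq_matrix <- function(freq_table) {
  pops <- unique(freq_table$pop)
  vids <- unique(freq_table$vid)
  matrix(freq_table$freq, nrow = length(pops),
         dimnames = list(pops, vids))
}
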