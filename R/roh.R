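#' Runs-of-homozygosity scan
#'
#' Sliding-window scan in the PLINK style. For each sample and chromosome
#' a window of `window_snps` variants slides one SNP at a time; a window
#' is called homozygous when it contains at most `het_allow` heterozygotes
#' and at most `miss_allow` missing calls. Each SNP is scored by the
#' fraction of overlapping windows that are homozygous, and SNPs with a
#' fraction of at least `window_threshold` are ROH-eligible. Maximal runs
#' of eligible SNPs — broken at heterozygous calls once `het_allow`
#' heterozygotes have been spent — are reported when they contain at least
#' `min_snps` SNPs and at most `miss_allow` missing calls, with bp bounds
#' at the member SNP positions.
#'
#' The defaults mirror array-based autozygosity scanning in endogamous
#' populations: minimum 100 SNPs, zero heterozygote allowance, 5 missing
#' calls, window threshold 0.05. The input panel is expected to be
#' LD-pruned (r-squared > `prune_r2` removed) and restricted to common
#' variants (MAF > `maf_min`); set `prefilter = TRUE` to apply both
#' internally.
#'
#' @param panel a [genotype_panel()].
#' @param min_snps minimum SNPs in a reported run (default 100).
#' @param het_allow heterozygotes allowed per window and per run
#'   (default 0).
#' @param miss_allow missing calls allowed per window and per run
#'   (default 5).
#' @param window_snps scanning window size in SNPs (default 50).
#' @param window_threshold minimum homozygous-window fraction for a SNP to
#'   be ROH-eligible (default 0.05).
#' @param maf_min,prune_r2 thresholds used when `prefilter = TRUE`.
#' @param prefilter apply the MAF filter and LD pruning internally
#'   (default `FALSE`: the caller has prepared the panel).
#' @return tibble `sample_id`, `chrom`, `start_pos`, `end_pos`, `n_snps`,
#'   `length_bp`, `n_het`, `n_missing`.
#' @export
roh_scan <- function(panel, min_snps = 100, het_allow = 0, miss_allow = 5,
                     window_snps = 50, window_threshold = 0.05,
                     maf_min = 0.05, prune_r2 = 0.5, prefilter = FALSE) {
  if (prefilter) {
    f <- variant_freq_b(panel)
    panel <- subset_panel(panel,
                          variants = !is.nan(f) & pmin(f, 1 - f) > maf_min)
    panel <- subset_panel(panel,
                          variants = panel$variants$vid %in%
                            ld_prune(panel, r2_max = prune_r2))
  }
  out <- list()
  chroms <- unique(panel$variants$chrom)
  for (ch in chroms) {
    vi <- which(panel$variants$chrom == ch)
    vi <- vi[order(panel$variants$pos[vi])]
    len <- length(vi)
    if (len < window_snps) {
      warn(sprintf("chromosome %s has %d < %d variants: skipped",
                   ch, len, window_snps))
      next
    }
    pos <- panel$variants$pos[vi]
    n_win <- len - window_snps + 1L
    for (si in seq_len(n_samples(panel))) {
      g <- panel$genotypes[si, vi]
      het <- as.integer(!is.na(g) & g == 1L)
      mis <- as.integer(is.na(g))
      roll <- function(x) {
        cs <- c(0L, cumsum(x))
        cs[(window_snps + 1):(len + 1)] - cs[1:n_win]
      }
      hom_win <- roll(het) <= het_allow & roll(mis) <= miss_allow
      # per-SNP homozygous-window fraction
      cw <- c(0L, cumsum(as.integer(hom_win)))
      lo <- pmax(1L, seq_len(len) - window_snps + 1L)
      hi <- pmin(n_win, seq_len(len))
      n_overlap <- hi - lo + 1L
      n_hom <- cw[hi + 1L] - cw[lo]
      eligible <- n_hom / n_overlap >= window_threshold
      # runs break at heterozygous calls (allowance het_allow per run)
      run_ok <- eligible & het == 0L
      r <- rle(run_ok)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values & r$lengths >= min_snps)) {
        seg <- starts[k]:ends[k]
        nmiss <- sum(mis[seg])
        if (nmiss > miss_allow) next
        out[[length(out) + 1L]] <- tibble::tibble(
          sample_id = panel$samples$sample_id[si], chrom = ch,
          start_pos = pos[seg[1]], end_pos = pos[seg[length(seg)]],
          n_snps = length(seg),
          length_bp = pos[seg[length(seg)]] - pos[seg[1]] + 1L,
          n_het = 0L, n_missing = nmiss
        )
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(sample_id = character(0), chrom = character(0),
                          start_pos = integer(0), end_pos = integer(0),
                          n_snps = integer(0), length_bp = integer(0),
                          n_het = integer(0), n_missing = integer(0)))
  }
  dplyr::bind_rows(out)
}

#' Per-sample inbreeding coefficient
#'
#' Method-of-moments F from the homozygote excess:
#' `F = (O - E) / (N - E)`, where `O` is the observed homozygote count
#' over the sample's non-missing genotypes, `E` the expected count
#' `sum(1 - 2 p q * 2n/(2n - 1))` under Hardy-Weinberg at the panel allele
#' frequencies (the `2n/(2n-1)` factor is the usual small-sample
#' correction on the expected heterozygosity, without which F is biased by
#' about `-1/(2n)`), and `N` the non-missing genotype count. Monomorphic
#' variants are excluded; `F` is undefined where `E = N`.
#'
#' @param panel a [genotype_panel()].
#' @return tibble `sample_id`, `o_hom`, `e_hom`, `n_geno`, `f`.
#' @export
inbreeding_f <- function(panel) {
  g <- panel$genotypes
  p <- variant_freq_b(panel)
  use <- !is.nan(p) & p > 0 & p < 1
  g <- g[, use, drop = FALSE]
  p <- p[use]
  n_geno_v <- colSums(!is.na(g))
  exp_hom <- 1 - 2 * p * (1 - p) * (2 * n_geno_v) / (2 * n_geno_v - 1)
  obs <- rowSums(g != 1L, na.rm = TRUE)
  ngeno <- rowSums(!is.na(g))
  ehom <- drop((!is.na(g)) %*% exp_hom)
  f <- ifelse(abs(ngeno - ehom) > 1e-12,
              (obs - ehom) / (ngeno - ehom), NA_real_)
  tibble::tibble(sample_id = panel$samples$sample_id,
                 o_hom = obs, e_hom = ehom, n_geno = ngeno, f = f)
}
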