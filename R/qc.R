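#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test from genotype counts: conditional on the allele
#' counts, the probability of every possible heterozygote count is
#' enumerated and the p-value is the sum of probabilities no larger than
#' that of the observed count. Monomorphic sites return 1.
#'
#' @param n_aa,n_ab,n_bb genotype counts (AA homozygote, heterozygote, BB
#'   homozygote).
#' @return exact two-sided p-value in `[0, 1]`.
#' @export
#' @examples
#' hwe_exact_test(57, 14, 50)
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n < 1) abort("at least one genotype required")
  na <- 2 * n_aa + n_ab              # count of allele a
  if (na == 0 || na == 2 * n) return(1)
  # feasible het counts share the parity of the allele count
  h <- seq.int(na %% 2, min(na, 2 * n - na), by = 2)
  # log P(h | n, na) up to a constant: multinomial x 2^h
  logp <- lfactorial(n) - lfactorial((na - h) / 2) - lfactorial(h) -
    lfactorial(n - (na + h) / 2) + h * log(2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_ab, h)]
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

hwe_p_per_variant <- function(geno) {
  apply(geno, 2, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  })
}

#' Allele-B frequency per variant (sample-wide)
#' @param panel a [genotype_panel()].
#' @return numeric vector, frequency of `allele_b` per variant.
#' @export
variant_freq_b <- function(panel) {
  colMeans(panel$genotypes, na.rm = TRUE) / 2
}

#' Quality-control filter for a genotype panel
#'
#' Applies the standard array-QC cascade in a fixed order so that removal
#' counts are reproducible: (1) variants with call rate below
#' `variant_call_rate`; (2) samples with missingness above `sample_missing`;
#' (3) variants failing the exact Hardy-Weinberg test at `hwe_p` (computed
#' across all retained samples); (4) optionally, variants with minor allele
#' frequency below `maf`. Per-step removal counts are recorded in the
#' `"qc_log"` attribute of the result.
#'
#' @param panel a [genotype_panel()].
#' @param variant_call_rate minimum variant call rate (default 0.99).
#' @param sample_missing maximum per-sample missingness (default 0.10).
#' @param hwe_p Hardy-Weinberg exact-test p-value threshold (default 1e-7);
#'   variants with p *below* the threshold are removed.
#' @param maf optional minor-allele-frequency threshold; variants with
#'   MAF < `maf` are removed.
#' @return the filtered [genotype_panel()] with attribute `qc_log`, a tibble
#'   of `step`, `removed`, `remaining`.
#' @export
filter_qc <- function(panel, variant_call_rate = 0.99,
                      sample_missing = 0.10, hwe_p = 1e-7, maf = NULL) {
  stopifnot(variant_call_rate >= 0, variant_call_rate <= 1,
            sample_missing >= 0, sample_missing <= 1)
  removed <- integer(0); remaining <- integer(0)
  note <- function(k) {
    removed <<- c(removed, k)
  }
  # 1. variant call rate
  cr <- colMeans(!is.na(panel$genotypes))
  keep_v <- cr >= variant_call_rate
  note(sum(!keep_v))
  panel <- subset_panel(panel, variants = keep_v)
  remaining <- c(remaining, n_variants(panel))
  # 2. sample missingness
  sm <- rowMeans(is.na(panel$genotypes))
  keep_s <- sm <= sample_missing
  note(sum(!keep_s))
  panel <- subset_panel(panel, samples = keep_s)
  remaining <- c(remaining, n_samples(panel))
  # 3. HWE
  if (n_variants(panel)) {
    p <- hwe_p_per_variant(panel$genotypes)
    keep_v <- is.na(p) | p >= hwe_p
    note(sum(!keep_v))
    panel <- subset_panel(panel, variants = keep_v)
  } else note(0L)
  remaining <- c(remaining, n_variants(panel))
  # 4. MAF
  if (!is.null(maf) && n_variants(panel)) {
    f <- variant_freq_b(panel)
    keep_v <- !is.nan(f) & pmin(f, 1 - f) >= maf
    note(sum(!keep_v))
    panel <- subset_panel(panel, variants = keep_v)
  } else note(0L)
  remaining <- c(remaining, n_variants(panel))
  if (n_variants(panel) == 0) {
    abort("all variants removed by QC; review thresholds")
  }
  attr(panel, "qc_log") <- tibble::tibble(
    step = c("variant_call_rate", "sample_missingness", "hwe", "maf"),
    removed = removed, remaining = remaining
  )
  panel
}

#' Pairwise IBD estimation (PI_HAT)
#'
#' Method-of-moments estimate of the IBD state probabilities for every
#' sample pair from identity-by-state counts and panel allele frequencies,
#' as used for relatedness screening. `PI_HAT = P(IBD=1)/2 + P(IBD=2)`.
#' Pairs with fewer than 50 informative (jointly genotyped, polymorphic)
#' variants are flagged `low_confidence`.
#'
#' @param panel a [genotype_panel()]; LD-pruned input is recommended.
#' @return tibble with columns `sample_i`, `sample_j`, `k0`, `k1`, `k2`,
#'   `pi_hat`, `n_informative`, `low_confidence`.
#' @export
estimate_pi_hat <- function(panel) {
  n <- n_samples(panel)
  if (n < 2) abort("need at least 2 samples")
  g <- panel$genotypes
  p <- variant_freq_b(panel)
  q <- 1 - p
  poly <- !is.na(p) & p > 0 & p < 1
  g <- g[, poly, drop = FALSE]
  p <- p[poly]; q <- q[poly]
  # per-variant expected IBS-state probabilities given IBD state
  e00 <- 2 * p^2 * q^2
  e01 <- 4 * p^3 * q + 4 * p * q^3
  e02 <- p^4 + q^4 + 4 * p^2 * q^2
  e11 <- 2 * p * q
  e12 <- p^2 + q^2
  ids <- panel$samples$sample_id
  out <- vector("list", n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) {
    gi <- g[i, ]
    for (j in seq.int(i + 1, n)) {
      gj <- g[j, ]
      m <- !is.na(gi) & !is.na(gj)
      d <- abs(gi[m] - gj[m])
      n_inf <- length(d)
      if (n_inf == 0) {
        k0 <- k1 <- k2 <- NA_real_
      } else {
        N0 <- sum(d == 2); N1 <- sum(d == 1); N2 <- sum(d == 0)
        S00 <- sum(e00[m]); S01 <- sum(e01[m]); S02 <- sum(e02[m])
        S11 <- sum(e11[m]); S12 <- sum(e12[m])
        k0 <- N0 / S00
        k1 <- (N1 - k0 * S01) / S11
        k2 <- (N2 - k0 * S02 - k1 * S12) / n_inf
        k0 <- min(max(k0, 0), 1)
        k1 <- min(max(k1, 0), 1)
        k2 <- min(max(k2, 0), 1)
      }
      k <- k + 1L
      out[[k]] <- tibble::tibble(
        sample_i = ids[i], sample_j = ids[j],
        k0 = k0, k1 = k1, k2 = k2,
        pi_hat = min(max(k1 / 2 + k2, 0), 1),
        n_informative = n_inf,
        low_confidence = n_inf < 50
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Remove one member of each related pair
#'
#' Flags pairs exceeding the PI_HAT threshold and greedily removes the
#' member with the higher missingness (ties: the later sample) until no
#' retained pair exceeds the threshold.
#'
#' @param panel a [genotype_panel()].
#' @param pairs output of [estimate_pi_hat()]; computed if missing.
#' @param threshold PI_HAT cut-off (default 0.35).
#' @return the panel with related samples removed; removed ids in attribute
#'   `"removed_samples"`.
#' @export
remove_related <- function(panel, pairs = NULL, threshold = 0.35) {
  if (is.null(pairs)) pairs <- estimate_pi_hat(panel)
  flagged <- pairs[!is.na(pairs$pi_hat) & pairs$pi_hat > threshold, ]
  miss <- rowMeans(is.na(panel$genotypes))
  names(miss) <- panel$samples$sample_id
  drop <- character(0)
  while (nrow(flagged)) {
    i <- flagged$sample_i[1]; j <- flagged$sample_j[1]
    victim <- if (miss[[i]] > miss[[j]]) i else j
    drop <- c(drop, victim)
    flagged <- flagged[flagged$sample_i != victim &
                         flagged$sample_j != victim, ]
  }
  out <- subset_panel(panel, samples = !panel$samples$sample_id %in% drop)
  attr(out, "removed_samples") <- drop
  out
}

#' Greedy windowed LD pruning
#'
#' Slides a window of `window_snps` variants in steps of `step_snps`; within
#' each window, while any retained pair has squared genotype correlation
#' above `r2_max`, the member with the lower call rate is removed (ties:
#' the later variant in panel order).
#'
#' @param panel a [genotype_panel()].
#' @param r2_max maximum tolerated r-squared (default 0.5).
#' @param window_snps,step_snps window size and slide step in variants.
#' @return character vector of retained variant ids, in panel order.
#' @export
ld_prune <- function(panel, r2_max = 0.5, window_snps = 50, step_snps = 5) {
  stopifnot(r2_max > 0, r2_max <= 1)
  m <- n_variants(panel)
  if (m < 2) return(panel$variants$vid)
  keep <- rep(TRUE, m)
  cr <- colMeans(!is.na(panel$genotypes))
  # windows never span chromosomes
  chrom_idx <- split(seq_len(m), factor(panel$variants$chrom,
                                        levels = unique(panel$variants$chrom)))
  for (idx in chrom_idx) {
    starts <- seq.int(1L, max(1L, length(idx) - 1L), by = step_snps)
    for (s in starts) {
      win <- idx[seq.int(s, min(s + window_snps - 1L, length(idx)))]
      repeat {
        cur <- win[keep[win]]
        if (length(cur) < 2) break
        r2 <- suppressWarnings(
          cor(panel$genotypes[, cur, drop = FALSE],
              use = "pairwise.complete.obs")^2)
        r2[!is.finite(r2)] <- 0
        diag(r2) <- 0
        off <- which(r2 > r2_max, arr.ind = TRUE)
        if (!nrow(off)) break
        off <- off[off[, 1] < off[, 2], , drop = FALSE]
        a <- cur[off[1, 1]]; b <- cur[off[1, 2]]
        victim <- if (cr[a] < cr[b]) a else b  # tie keeps earlier variant
        keep[victim] <- FALSE
      }
    }
  }
  panel$variants$vid[keep]
}
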