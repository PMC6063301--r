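#' Weir-Cockerham per-variant FST from genotype counts
#'
#' Two-population method-of-moments estimator (Weir & Cockerham 1984) using
#' observed heterozygosity. Inputs are per-variant genotype count tables
#' (dosage 0/1/2 of the same allele in both populations). Per variant the
#' variance components `a` (among populations), `b` (among individuals
#' within populations) and `c` (within individuals) are returned together
#' with `fst = a/(a+b+c)`. The estimate is undefined (`NA`) where the
#' denominator is zero (monomorphic in both populations) or where either
#' population has fewer than two genotyped samples; negative estimates are
#' preserved (clamping to zero happens only inside [pbs()]).
#'
#' @param counts1,counts2 data frames or matrices with columns `n0`, `n1`,
#'   `n2`: per-variant genotype counts for each population.
#' @return tibble with columns `a`, `b`, `c`, `fst`.
#' @export
weir_cockerham_fst <- function(counts1, counts2) {
  c1 <- as.matrix(counts1); c2 <- as.matrix(counts2)
  stopifnot(ncol(c1) == 3, ncol(c2) == 3, nrow(c1) == nrow(c2))
  n1 <- rowSums(c1); n2 <- rowSums(c2)
  ok <- n1 >= 2 & n2 >= 2
  p1 <- (c1[, 2] + 2 * c1[, 3]) / (2 * n1)
  p2 <- (c2[, 2] + 2 * c2[, 3]) / (2 * n2)
  h1 <- c1[, 2] / n1
  h2 <- c2[, 2] / n2

  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2

  denom <- a + b + cc
  fst <- ifelse(ok & abs(denom) > 0, a / denom, NA_real_)
  a[!ok] <- b[!ok] <- cc[!ok] <- NA_real_
  tibble::tibble(a = a, b = b, c = cc, fst = fst)
}

genotype_counts <- function(panel, sample_idx) {
  g <- panel$genotypes[sample_idx, , drop = FALSE]
  cbind(n0 = colSums(g == 0L, na.rm = TRUE),
        n1 = colSums(g == 1L, na.rm = TRUE),
        n2 = colSums(g == 2L, na.rm = TRUE))
}

#' Per-variant FST between two sample groups of a panel
#'
#' @param panel a [genotype_panel()].
#' @param group1,group2 population codes or sample indices defining the two
#'   groups.
#' @return tibble `vid`, `a`, `b`, `c`, `fst`.
#' @export
pairwise_fst <- function(panel, group1, group2) {
  idx <- function(g) if (is.character(g)) population_samples(panel, g) else g
  out <- weir_cockerham_fst(genotype_counts(panel, idx(group1)),
                            genotype_counts(panel, idx(group2)))
  dplyr::bind_cols(tibble::tibble(vid = panel$variants$vid), out)
}

#' Population Branch Statistic
#'
#' Transforms pairwise FST values into branch lengths `T = -ln(1 - FST)`
#' and isolates the focal (high-altitude) branch:
#' `PBS = (T_HC + T_HO - T_CO) / 2`, where H is the focal group, C the
#' closest lowland reference and O the outgroup. Negative FST estimates are
#' clamped to 0 and values at or above 1 to `1 - 1e-12` before the log.
#' Any missing FST yields a missing PBS.
#'
#' @param fst_hc,fst_ho,fst_co per-variant FST vectors for the three pairs
#'   (focal-close, focal-outgroup, close-outgroup).
#' @return tibble with columns `t_hc`, `t_ho`, `t_co`, `pbs`.
#' @export
#' @examples
#' pbs(0.1, 0.1, 0.1)  # pbs = -log(0.9)/2
pbs <- function(fst_hc, fst_ho, fst_co) {
  branch <- function(f) {
    f <- pmin(pmax(f, 0), 1 - 1e-12)
    -log(1 - f)
  }
  t_hc <- branch(fst_hc); t_ho <- branch(fst_ho); t_co <- branch(fst_co)
  tibble::tibble(t_hc = t_hc, t_ho = t_ho, t_co = t_co,
                 pbs = (t_hc + t_ho - t_co) / 2)
}
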