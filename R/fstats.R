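#' Weighted delete-one-block jackknife
#'
#' Standard-error estimation for a weighted-mean statistic over contiguous
#' SNP blocks, robust to local LD. Given block-level values and weights
#' (SNP counts), the overall estimate is the weighted mean; the standard
#' error uses the weighted delete-one jackknife (Busing et al. 1999)
#' pseudovalues. Two equal-weight blocks with values `a`, `b` give
#' `SE = |a - b| / 2`.
#'
#' @param values per-block statistic values.
#' @param weights per-block weights (e.g. SNP counts); equal by default.
#' @return list with `estimate`, `se`, `n_blocks`.
#' @export
block_jackknife <- function(values, weights = rep(1, length(values))) {
  stopifnot(length(values) == length(weights), all(weights > 0))
  g <- length(values)
  if (g < 2) abort("need at least 2 blocks for a jackknife SE")
  w_tot <- sum(weights)
  est <- sum(weights * values) / w_tot
  loo <- (sum(weights * values) - weights * values) / (w_tot - weights)
  jackknife_se(est, loo, weights)
}

# Busing et al. (1999) weighted jackknife from delete-one estimates
jackknife_se <- function(est, loo, weights) {
  g <- length(loo)
  w_tot <- sum(weights)
  h <- w_tot / weights
  theta_j <- g * est - sum((1 - weights / w_tot) * loo)
  tau <- h * est - (h - 1) * loo
  var_j <- sum((tau - theta_j)^2 / (h - 1)) / g
  list(estimate = est, se = sqrt(var_j), n_blocks = g)
}

# split SNP indices into contiguous blocks of `blocks` SNPs (last short)
snp_blocks <- function(n_snps, blocks) {
  if (n_snps < 1) abort("no usable SNPs")
  rep(seq_len(ceiling(n_snps / blocks)), each = blocks)[seq_len(n_snps)]
}

fstat_result <- function(jk, n_snps) {
  tibble::tibble(value = jk$estimate, se = jk$se,
                 z = jk$estimate / jk$se,
                 n_blocks = jk$n_blocks, n_snps_used = n_snps)
}

#' Admixture f3 statistic
#'
#' `f3(target; A, B) = mean[(c - a)(c - b)] - correction`, where the
#' correction `c(1-c)/(2 n_c - 1)` removes the sampling-noise bias of the
#' target frequency estimate (`n_c` diploid samples). A significantly
#' negative value (conventionally `Z <= -3`) indicates the target is
#' admixed between sources related to A and B. Standard errors come from a
#' weighted delete-one jackknife over contiguous blocks of `blocks` SNPs.
#'
#' @param freq_target,freq_a,freq_b per-SNP derived-allele frequencies.
#' @param n_target diploid sample count(s) behind `freq_target` (scalar or
#'   per-SNP vector), used for the bias correction.
#' @param blocks jackknife block size in SNPs (default 500).
#' @return one-row tibble `value`, `se`, `z`, `n_blocks`, `n_snps_used`.
#' @export
f3_admixture <- function(freq_target, freq_a, freq_b, n_target,
                         blocks = 500) {
  use <- stats::complete.cases(freq_target, freq_a, freq_b)
  # drop SNPs monomorphic in all three populations
  mono <- (freq_target == 0 & freq_a == 0 & freq_b == 0) |
    (freq_target == 1 & freq_a == 1 & freq_b == 1)
  use <- use & !ifelse(is.na(mono), TRUE, mono)
  cfr <- freq_target[use]; a <- freq_a[use]; b <- freq_b[use]
  nt <- if (length(n_target) == 1) n_target else n_target[use]
  if (sum(use) < 1000) {
    warn(sprintf("only %d usable SNPs for f3: estimate will be noisy",
                 sum(use)))
  }
  terms <- (cfr - a) * (cfr - b) - cfr * (1 - cfr) / (2 * nt - 1)
  blk <- snp_blocks(length(terms), blocks)
  bv <- tapply(terms, blk, mean)
  bw <- tabulate(blk)
  fstat_result(block_jackknife(as.numeric(bv), bw), length(terms))
}

#' Outgroup f3 statistic
#'
#' `f3(outgroup; X, ref) = mean[(o - x)(o - ref)]`: the shared drift of X
#' and ref since their divergence from the outgroup. Larger values mean
#' more shared history. No target bias correction is applied (the outgroup
#' is held fixed). Warns when the outgroup frequencies correlate > 0.9
#' with X, a sign the "outgroup" is not one.
#'
#' @param freq_outgroup,freq_x,freq_ref per-SNP derived-allele frequencies.
#' @param blocks jackknife block size in SNPs (default 500).
#' @return one-row tibble as in [f3_admixture()].
#' @export
f3_outgroup <- function(freq_outgroup, freq_x, freq_ref, blocks = 500) {
  use <- stats::complete.cases(freq_outgroup, freq_x, freq_ref)
  o <- freq_outgroup[use]; x <- freq_x[use]; r <- freq_ref[use]
  if (sd(o) > 0 && sd(x) > 0 && cor(o, x) > 0.9) {
    warn("outgroup frequencies correlate > 0.9 with X: check population roles")
  }
  terms <- (o - x) * (o - r)
  blk <- snp_blocks(length(terms), blocks)
  bv <- tapply(terms, blk, mean)
  bw <- tabulate(blk)
  fstat_result(block_jackknife(as.numeric(bv), bw), length(terms))
}

#' Four-population D statistic
#'
#' `D(W, X; Y, Z) = sum[(w - x)(y - z)] / sum[(w + x - 2wx)(y + z - 2yz)]`
#' over SNPs with all four frequencies defined. A nonzero D rejects the
#' tree ((W,X),(Y,Z)) symmetric in Y/Z, indicating gene flow. The standard
#' error and Z score come from a weighted delete-one jackknife over
#' contiguous blocks of `blocks` SNPs, jackknifing the ratio.
#'
#' @param freq_w,freq_x,freq_y,freq_z per-SNP derived-allele frequencies.
#' @param blocks jackknife block size in SNPs (default 500).
#' @return one-row tibble as in [f3_admixture()].
#' @export
d_statistic <- function(freq_w, freq_x, freq_y, freq_z, blocks = 500) {
  use <- stats::complete.cases(freq_w, freq_x, freq_y, freq_z)
  w <- freq_w[use]; x <- freq_x[use]; y <- freq_y[use]; z <- freq_z[use]
  num <- (w - x) * (y - z)
  den <- (w + x - 2 * w * x) * (y + z - 2 * y * z)
  if (sum(den) == 0) abort("D statistic undefined: zero denominator")
  blk <- snp_blocks(length(num), blocks)
  if (max(blk) < 2) abort("need at least 2 jackknife blocks")
  ns <- tapply(num, blk, sum)
  ds <- tapply(den, blk, sum)
  est <- sum(num) / sum(den)
  loo <- (sum(num) - ns) / (sum(den) - ds)
  jk <- jackknife_se(est, as.numeric(loo), tabulate(blk))
  fstat_result(jk, length(num))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper triangles, with a two-sided
#' permutation p-value under joint row/column permutations of the second
#' matrix: `p` is the proportion of permutations (identity included) whose
#' `|r|` is at least the observed `|r|`. When the number of objects is
#' small enough that all `n!` permutations fit in `n_perm`, the exact
#' enumeration is used; otherwise `n_perm` random permutations are drawn
#' (seed-deterministic).
#'
#' @param m1,m2 square symmetric matrices over the same objects.
#' @param n_perm number of random permutations (default 9999).
#' @param seed optional seed for the permutation draw.
#' @return list with `r`, `p`, `n_perm_used`, `exact`.
#' @export
mantel_test <- function(m1, m2, n_perm = 9999, seed = NULL) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  n <- nrow(m1)
  stopifnot(all(dim(m1) == dim(m2)), n == ncol(m1))
  if (n < 4) abort("need at least 4 objects")
  if (max(abs(m1 - t(m1))) > 1e-8 || max(abs(m2 - t(m2))) > 1e-8) {
    abort("matrices must be symmetric")
  }
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  if (sd(v1) == 0 || sd(m2[ut]) == 0) {
    abort("constant distance matrix: correlation undefined")
  }
  r_obs <- cor(v1, m2[ut])
  perm_r <- function(ix) cor(v1, m2[ix, ix][ut])
  if (factorial(n) <= n_perm) {
    perms <- all_permutations(n)
    rs <- apply(perms, 1, perm_r)   # includes the identity
    p <- mean(abs(rs) >= abs(r_obs) - 1e-12)
    list(r = r_obs, p = p, n_perm_used = nrow(perms), exact = TRUE)
  } else {
    rs <- with_seed_if(seed, vapply(seq_len(n_perm), function(i)
      perm_r(sample.int(n)), 0))
    p <- (sum(abs(rs) >= abs(r_obs) - 1e-12) + 1) / (n_perm + 1)
    list(r = r_obs, p = p, n_perm_used = n_perm, exact = FALSE)
  }
}
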