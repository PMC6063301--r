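#' Genomic relationship (kinship) matrix
#'
#' Standardized-genotype covariance `K = Z Z' / m`, with each variant's
#' dosages centred by `2 p` and scaled by `sqrt(2 p (1-p))`, `p` being the
#' sample allele frequency. Missing genotypes are mean-imputed before
#' standardization (their standardized value is 0), keeping the matrix
#' usable as a random-effect covariance without dropping samples.
#' Monomorphic variants are excluded.
#'
#' @param panel a [genotype_panel()].
#' @return n x n symmetric matrix with sample ids as dimnames; the number
#'   of variants used is in attribute `"n_variants_used"`.
#' @export
kinship_grm <- function(panel) {
  if (n_samples(panel) < 2) abort("need at least 2 samples")
  g <- panel$genotypes
  p <- colMeans(g, na.rm = TRUE) / 2
  use <- !is.na(p) & p > 0 & p < 1
  g <- g[, use, drop = FALSE]
  p <- p[use]
  m <- ncol(g)
  if (m == 0) abort("no polymorphic variants for the kinship matrix")
  z <- sweep(g, 2, 2 * p, "-")
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  z[is.na(z)] <- 0
  k <- tcrossprod(z) / m
  dimnames(k) <- list(panel$samples$sample_id, panel$samples$sample_id)
  attr(k, "n_variants_used") <- m
  k
}

#' Squared genotype correlation between two variants
#'
#' Squared Pearson correlation of dosages over samples genotyped for both
#' variants; `NA` when fewer than two complete pairs remain or either
#' vector is constant. Sign-invariant: recoding one variant as `2 - g`
#' leaves the value unchanged.
#'
#' @param g1,g2 dosage vectors.
#' @return r-squared, or `NA`.
#' @export
genotype_r2 <- function(g1, g2) {
  m <- !is.na(g1) & !is.na(g2)
  if (sum(m) < 2) return(NA_real_)
  if (sd(g1[m]) == 0 || sd(g2[m]) == 0) return(NA_real_)
  cor(g1[m], g2[m])^2
}
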