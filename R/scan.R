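#' Spearman correlation scan of derived frequency against altitude
#'
#' Per variant, the Spearman rank correlation (midranks, ties allowed)
#' between per-population derived allele frequency and residence altitude,
#' with a two-sided p-value from the t-approximation on `n - 2` degrees of
#' freedom. Variants observed in fewer than four populations, or with
#' constant frequency across populations, are excluded from the test count.
#' The Bonferroni flag requires `p < alpha / N` with `N` the number of
#' variants actually tested.
#'
#' @param freq_table output of [allele_frequencies()], restricted to the
#'   populations that should enter the scan.
#' @param populations a [population_panel()] supplying altitudes.
#' @param alpha family-wise error rate for the Bonferroni flag
#'   (default 0.05).
#' @param exact if `TRUE`, compute exact permutation p-values by full
#'   enumeration (only for at most 8 populations).
#' @return tibble `vid`, `chrom`, `pos`, `n_pops`, `rho`, `p_spearman`,
#'   `spearman_sig`; the test count is in attribute `"n_tests"`.
#' @export
spearman_altitude_scan <- function(freq_table, populations, alpha = 0.05,
                                   exact = FALSE) {
  fmat <- freq_matrix(freq_table)
  alt <- populations$altitude_m[match(rownames(fmat), populations$code)]
  if (anyNA(alt)) abort("population missing from the population panel")
  meta <- dplyr::distinct(freq_table, .data$vid, .data$chrom, .data$pos)

  one <- function(f) {
    ok <- !is.na(f)
    n <- sum(ok)
    if (n < 4) return(c(n, NA, NA))
    fr <- f[ok]; ar <- alt[ok]
    if (length(unique(fr)) < 2 || length(unique(ar)) < 2) {
      return(c(n, NA, NA))
    }
    rf <- rank(fr); ra <- rank(ar)
    rho <- cor(rf, ra)
    if (exact) {
      if (n > 8) abort("exact permutation only supported for <= 8 populations")
      perms <- all_permutations(n)
      rhos <- apply(perms, 1, function(ix) cor(rf[ix], ra))
      p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    } else {
      if (abs(rho) >= 1) {
        p <- 0
      } else {
        tt <- rho * sqrt((n - 2) / (1 - rho^2))
        p <- 2 * pt(-abs(tt), n - 2)
      }
    }
    c(n, rho, p)
  }
  res <- unname(apply(fmat, 2, one))
  n_tests <- sum(!is.na(res[3, ]))
  out <- tibble::tibble(
    vid = colnames(fmat),
    n_pops = as.integer(res[1, ]),
    rho = res[2, ],
    p_spearman = res[3, ],
    spearman_sig = !is.na(res[3, ]) & res[3, ] < alpha / max(n_tests, 1)
  ) |>
    dplyr::left_join(meta, by = "vid") |>
    dplyr::relocate("chrom", "pos", .after = "vid")
  attr(out, "n_tests") <- n_tests
  out
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Fit the null linear mixed model for altitude association
#'
#' REML fit of `altitude = intercept + g + e` with `g ~ N(0, sigma_g^2 K)`
#' and `e ~ N(0, sigma_e^2 I)`, by one-dimensional optimization over the
#' variance ratio `delta = sigma_e^2 / sigma_g^2` on the eigenbasis of the
#' kinship matrix. The fit is reused unchanged for every per-variant test
#' (the EMMAX approximation). Negative kinship eigenvalues are clamped to
#' zero.
#'
#' @param altitude numeric phenotype vector (each sample's population
#'   altitude, metres).
#' @param kinship symmetric kinship matrix from [kinship_grm()].
#' @return an object of class `lmm_null_fit` with variance components,
#'   `h2` (fraction of phenotypic variance attributed to kinship), and the
#'   eigen-rotation reused by [lmm_assoc_scan()].
#' @export
lmm_fit_null <- function(altitude, kinship) {
  n <- length(altitude)
  stopifnot(nrow(kinship) == n, ncol(kinship) == n)
  eig <- eigen(kinship, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  u <- eig$vectors
  ty <- drop(crossprod(u, altitude))
  tx <- drop(crossprod(u, rep(1, n)))

  reml_ll <- function(log_delta) {
    w <- d + exp(log_delta)
    xwx <- sum(tx^2 / w)
    beta <- sum(tx * ty / w) / xwx
    rss <- sum((ty - tx * beta)^2 / w)
    sg2 <- rss / (n - 1)
    -0.5 * ((n - 1) * log(sg2) + sum(log(w)) + log(xwx))
  }
  opt <- optimize(reml_ll, c(-14, 14), maximum = TRUE, tol = 1e-8)
  if (!is.finite(opt$objective)) {
    abort("non-finite REML likelihood over the delta grid [-14, 14] (log)")
  }
  delta <- exp(opt$maximum)
  w <- d + delta
  xwx <- sum(tx^2 / w)
  beta0 <- sum(tx * ty / w) / xwx
  sg2 <- sum((ty - tx * beta0)^2 / w) / (n - 1)
  se2 <- delta * sg2
  structure(list(
    sigma_g2 = sg2, sigma_e2 = se2, delta = delta,
    h2 = sg2 * mean(d) / (sg2 * mean(d) + se2),
    eigenvalues = d, rotation = u, ty = ty, tx = tx,
    n = n, reml = opt$objective
  ), class = "lmm_null_fit")
}

#' @export
print.lmm_null_fit <- function(x, ...) {
  cat("<lmm_null_fit>\n")
  cat(sprintf("  sigma_g^2 = %.4g, sigma_e^2 = %.4g (delta = %.4g)\n",
              x$sigma_g2, x$sigma_e2, x$delta))
  cat(sprintf("  variance fraction via kinship (h2): %.3f\n", x$h2))
  invisible(x)
}

#' Mixed-model association scan (EMMAX approximation)
#'
#' Per-variant generalized least squares of altitude on genotype dosage
#' with the covariance structure fixed from the null fit: variance
#' components are estimated once and reused for every variant, the
#' defining shortcut of the approach. Missing dosages are mean-imputed;
#' monomorphic variants and variants with 50% or more missingness are
#' skipped. The Wald test is two-sided; `lmm_sig` flags
#' `p < sig_threshold`.
#'
#' @param panel a [genotype_panel()].
#' @param null_fit an [lmm_fit_null()] object fitted on the same samples.
#' @param sig_threshold genome-wide significance level (default 5e-8).
#' @return tibble `vid`, `chrom`, `pos`, `beta_lmm`, `se_lmm`, `p_lmm`,
#'   `lmm_sig`.
#' @export
lmm_assoc_scan <- function(panel, null_fit, sig_threshold = 5e-8) {
  stopifnot(inherits(null_fit, "lmm_null_fit"),
            n_samples(panel) == null_fit$n)
  g <- panel$genotypes
  miss_frac <- colMeans(is.na(g))
  p <- colMeans(g, na.rm = TRUE) / 2
  usable <- miss_frac < 0.5 & !is.na(p) & p > 0 & p < 1
  storage.mode(g) <- "double"
  # mean-impute missing dosages
  if (anyNA(g)) {
    na_idx <- which(is.na(g), arr.ind = TRUE)
    g[na_idx] <- 2 * p[na_idx[, 2]]
  }
  tg <- crossprod(null_fit$rotation, g)
  w <- null_fit$eigenvalues + null_fit$delta
  tx <- null_fit$tx; ty <- null_fit$ty
  n <- null_fit$n

  a11 <- sum(tx^2 / w)
  b1 <- sum(tx * ty / w)
  yy <- sum(ty^2 / w)
  a12 <- drop(crossprod(tx / w, tg))
  a22 <- colSums(tg^2 / w)
  b2 <- drop(crossprod(ty / w, tg))

  det <- a11 * a22 - a12^2
  beta <- (a11 * b2 - a12 * b1) / det
  beta1 <- (a22 * b1 - a12 * b2) / det
  rss <- yy - (beta1 * b1 + beta * b2)
  sigma2 <- rss / (n - 2)
  se <- sqrt(pmax(sigma2 * a11 / det, 0))
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), n - 2)
  pval[!usable] <- NA_real_
  beta[!usable] <- NA_real_
  se[!usable] <- NA_real_
  tibble::tibble(
    vid = panel$variants$vid, chrom = panel$variants$chrom,
    pos = panel$variants$pos,
    beta_lmm = beta, se_lmm = se, p_lmm = pval,
    lmm_sig = !is.na(pval) & pval < sig_threshold
  )
}

#' PBS selection scan with empirical thresholding
#'
#' Pools three disjoint sample groups (focal high-altitude H, closest
#' lowland reference C, outgroup O), computes per-variant Weir-Cockerham
#' FST for the three pairs, transforms them into the Population Branch
#' Statistic, and flags variants in the top `(100 - percentile)%` of the
#' empirical PBS distribution: the threshold is the k-th largest finite
#' value with `k = ceiling(N * (1 - percentile/100))`, and all values at or
#' above it are flagged (ties keep all tied variants).
#'
#' @param panel a [genotype_panel()].
#' @param group_h,group_c,group_o population codes or sample indices for
#'   the three groups; they must be disjoint.
#' @param percentile empirical percentile for significance
#'   (default 99.99).
#' @return tibble `vid`, `chrom`, `pos`, `fst_hc`, `fst_ho`, `fst_co`,
#'   `pbs`, `pbs_sig`; the threshold is in attribute `"pbs_threshold"`.
#' @export
pbs_scan <- function(panel, group_h, group_c, group_o, percentile = 99.99) {
  idx <- function(g) if (is.character(g)) population_samples(panel, g) else g
  ih <- idx(group_h); ic <- idx(group_c); io <- idx(group_o)
  if (length(intersect(ih, ic)) || length(intersect(ih, io)) ||
      length(intersect(ic, io))) {
    abort("the three PBS groups must be disjoint")
  }
  ch <- genotype_counts(panel, ih)
  cc <- genotype_counts(panel, ic)
  co <- genotype_counts(panel, io)
  f_hc <- weir_cockerham_fst(ch, cc)$fst
  f_ho <- weir_cockerham_fst(ch, co)$fst
  f_co <- weir_cockerham_fst(cc, co)$fst
  pb <- pbs(f_hc, f_ho, f_co)$pbs
  finite <- is.finite(pb)
  n_fin <- sum(finite)
  if (n_fin < 10000) {
    warn(sprintf(
      "only %d finite PBS values: the %.2f%% empirical threshold is unstable",
      n_fin, percentile))
  }
  k <- max(1L, ceiling(n_fin * (1 - percentile / 100)))
  thr <- sort(pb[finite], decreasing = TRUE)[k]
  out <- tibble::tibble(
    vid = panel$variants$vid, chrom = panel$variants$chrom,
    pos = panel$variants$pos,
    fst_hc = f_hc, fst_ho = f_ho, fst_co = f_co,
    pbs = pb, pbs_sig = finite & pb >= thr
  )
  attr(out, "pbs_threshold") <- thr
  out
}
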