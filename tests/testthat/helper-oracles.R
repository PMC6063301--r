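`%||%` <- function(a, b) if (is.null(a)) b else a

# --- Independent oracles, deliberately written in a different style -----

# Exact HWE: probability of each heterozygote count from the closed-form
# conditional distribution  P(nab | n, na) = n! na! nb! 2^nab /
# ((2n)! * naa! * nab! * nbb!), evaluated with plain factorials.
oracle_hwe_p <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  na <- 2 * naa + nab
  nb <- 2 * n - na
  if (na == 0 || nb == 0) return(1)
  hs <- seq(na %% 2, min(na, nb), by = 2)
  logprob <- function(h) {
    a <- (na - h) / 2
    b <- (nb - h) / 2
    (lfactorial(n) + lfactorial(na) + lfactorial(nb) + h * log(2)) -
      (lfactorial(2 * n) + lfactorial(a) + lfactorial(h) + lfactorial(b))
  }
  pr <- exp(vapply(hs, logprob, 0))
  stopifnot(abs(sum(pr) - 1) < 1e-8)   # closed form must be a distribution
  p_obs <- pr[which(hs == nab)]
  sum(pr[pr <= p_obs + 1e-12 * p_obs])
}

# Weir & Cockerham (1984) two-population estimator, spreadsheet style:
# scalar arithmetic from genotype counts, one quantity per line.
oracle_wc_fst <- function(naa1, nab1, nbb1, naa2, nab2, nbb2) {
  n1 <- naa1 + nab1 + nbb1
  n2 <- naa2 + nab2 + nbb2
  p1 <- (nab1 + 2 * nbb1) / (2 * n1)
  p2 <- (nab2 + 2 * nbb2) / (2 * n2)
  h1 <- nab1 / n1
  h2 <- nab2 / n2
  r <- 2
  nbar <- (n1 + n2) / 2
  csq <- ((n1 - nbar)^2 + (n2 - nbar)^2) / ((r - 1) * nbar^2) # squared CV
  nc <- nbar * (1 - csq / r)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  ssq <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  term <- pbar * (1 - pbar) - ssq * (r - 1) / r
  a <- (nbar / nc) * (ssq - (term - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (term - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc, fst = a / (a + b + cc))
}

# all permutations of 1..n by recursive insertion (independent of the
# package's generator)
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- oracle_perms(n - 1L)
  out <- list()
  for (p in smaller) {
    for (slot in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = slot)
    }
  }
  out
}

# Mantel p by exhaustive enumeration over all n! joint permutations
oracle_mantel <- function(m1, m2) {
  ut <- upper.tri(m1)
  r_obs <- cor(m1[ut], m2[ut])
  rs <- vapply(oracle_perms(nrow(m1)), function(p) {
    cor(m1[ut], m2[p, p][ut])
  }, 0)
  list(r = r_obs, p = mean(abs(rs) >= abs(r_obs) - 1e-12))
}

# exact two-sided Spearman p by enumeration of all rank permutations
oracle_spearman_exact <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  r_obs <- cor(rx, ry)
  rs <- vapply(oracle_perms(length(x)), function(p) cor(rx[p], ry), 0)
  mean(abs(rs) >= abs(r_obs) - 1e-12)
}

# chi-square upper tail by numerical integration of the density
oracle_chisq_upper <- function(q, df) {
  stats::integrate(function(x) stats::dchisq(x, df), q, Inf,
                   rel.tol = 1e-10)$value
}
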