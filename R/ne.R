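GENERATION_YEARS <- 29

#' Fit the hyperbolic LD-decay model to binned data
#'
#' Nonlinear least squares of `y = 1/(alpha + beta * c)` over bin means,
#' where `y` is the sample-size-adjusted squared correlation
#' (`r2 - 1/n`) and `c` the recombination distance in Morgans. Under the
#' drift expectation `E[y] = 1/(alpha + 4 Ne c)`, the long-term effective
#' population size is `Ne = beta / 4`. Each bin also yields a
#' time-resolved size `Ne_t = (1/y - alpha) / (4c)` at `t = 1/(2c)`
#' generations ago; the harmonic mean over bins with positive estimates
#' summarizes the trajectory. Generations are converted to years at 29
#' years per generation.
#'
#' @param c recombination distances (Morgans), one per bin, ascending.
#' @param y adjusted mean r-squared per bin.
#' @param n_pairs optional per-bin pair counts (recorded).
#' @return an object of class `ne_trajectory`: list with `alpha`, `beta`,
#'   `ne_long_term`, `ne_harmonic`, `generation_years`, and a `bins`
#'   tibble (`c`, `y`, `t_generations`, `t_years`, `ne_t`, `n_pairs`).
#' @export
fit_ld_decay <- function(c, y, n_pairs = NA_integer_) {
  stopifnot(length(c) == length(y), all(c > 0))
  use <- is.finite(y) & y > 0
  if (sum(use) < 3) abort("need at least 3 usable bins to fit the decay model")
  cf <- c[use]; yf <- y[use]
  # linearized start: 1/y = alpha + beta c
  start <- stats::coef(stats::lm(I(1 / yf) ~ cf))
  start <- pmax(as.numeric(start), 1e-6)
  rss_of <- function(par) sum((yf - 1 / (par[1] + par[2] * cf))^2)
  fit <- tryCatch(
    minpack.lm::nlsLM(yf ~ 1 / (alpha + beta * cf),
                      start = list(alpha = start[1], beta = start[2]),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    est <- stats::coef(fit)
    rss <- sum(stats::resid(fit)^2)
  } else {
    # near-collinear gradients (e.g. almost-flat decay): direct RSS descent
    opt <- stats::optim(start, rss_of, method = "L-BFGS-B",
                        lower = c(1e-8, 1e-8),
                        control = list(factr = 1e3, maxit = 500))
    if (!is.finite(opt$value)) {
      abort(paste0("LD-decay fit failed; residual range of linearized ",
                   "start: ",
                   paste(signif(range(1 / yf - start[1] - start[2] * cf), 3),
                         collapse = " to ")))
    }
    est <- c(alpha = opt$par[1], beta = opt$par[2])
    rss <- opt$value
  }
  alpha <- est[["alpha"]]; beta <- est[["beta"]]
  ne_t <- ifelse(y > 0, pmax((1 / y - alpha) / (4 * c), 0), NA_real_)
  bins <- tibble::tibble(
    c = c, y = y,
    t_generations = 1 / (2 * c),
    t_years = GENERATION_YEARS / (2 * c),
    ne_t = ne_t,
    n_pairs = n_pairs
  )
  pos <- !is.na(ne_t) & ne_t > 0
  structure(list(
    alpha = alpha, beta = beta,
    ne_long_term = beta / 4,
    ne_harmonic = if (any(pos)) length(ne_t[pos]) / sum(1 / ne_t[pos])
                  else NA_real_,
    generation_years = GENERATION_YEARS,
    bins = bins,
    rss = rss
  ), class = "ne_trajectory")
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat("<ne_trajectory>\n")
  cat(sprintf("  y = 1/(alpha + beta c): alpha = %.4g, beta = %.4g\n",
              x$alpha, x$beta))
  cat(sprintf("  long-term Ne = beta/4 = %.1f; harmonic-mean Ne = %.1f\n",
              x$ne_long_term, x$ne_harmonic))
  cat(sprintf("  %d bins, t = 1/(2c) spanning %.0f-%.0f generations\n",
              nrow(x$bins), min(x$bins$t_generations),
              max(x$bins$t_generations)))
  invisible(x)
}

#' Effective population size from LD decay in a genotype panel
#'
#' Pairs of variants on the same chromosome are binned by recombination
#' distance (from the `cm` map column; a constant 1 cM/Mb map is assumed
#' when absent), each pair contributes the adjusted squared correlation
#' `r2 - 1/n` with `n = 2 x samples` (the chromosome sample size), and the
#' binned means are fed to [fit_ld_decay()].
#'
#' @param panel a [genotype_panel()].
#' @param population population code to estimate for (single population;
#'   use subsetting for pooled estimates).
#' @param c_breaks bin edges in Morgans (ascending); pairs outside the
#'   range are ignored.
#' @param min_n minimum samples in the population (default 10): smaller
#'   samples make the harmonic mean unstable.
#' @return an `ne_trajectory` (see [fit_ld_decay()]).
#' @export
ne_from_ld <- function(panel, population,
                       c_breaks = seq(0.0005, 0.05, length.out = 26),
                       min_n = 10) {
  si <- population_samples(panel, population)
  if (length(si) < min_n) {
    abort(sprintf("population %s has %d < %d samples",
                  population, length(si), min_n))
  }
  g <- panel$genotypes[si, , drop = FALSE]
  storage.mode(g) <- "double"
  cm <- panel$variants[["cm"]] %||% (panel$variants$pos * 1e-6)
  cm[is.na(cm)] <- panel$variants$pos[is.na(cm)] * 1e-6
  n_chrom_samples <- 2 * length(si)

  mids <- (c_breaks[-1] + c_breaks[-length(c_breaks)]) / 2
  sums <- numeric(length(mids)); counts <- integer(length(mids))
  for (ch in unique(panel$variants$chrom)) {
    vi <- which(panel$variants$chrom == ch)
    if (length(vi) < 2) next
    gc <- g[, vi, drop = FALSE]
    keep <- apply(gc, 2, function(x) sd(x, na.rm = TRUE) > 0)
    vi <- vi[keep]; gc <- gc[, keep, drop = FALSE]
    if (length(vi) < 2) next
    r2 <- suppressWarnings(cor(gc, use = "pairwise.complete.obs")^2)
    d <- abs(outer(cm[vi], cm[vi], "-")) / 100   # Morgans
    ut <- upper.tri(d)
    dv <- d[ut]; rv <- r2[ut]
    ok <- is.finite(rv) & dv >= c_breaks[1] & dv <= c_breaks[length(c_breaks)]
    bin <- findInterval(dv[ok], c_breaks, rightmost.closed = TRUE)
    yv <- rv[ok] - 1 / n_chrom_samples
    s <- tapply(yv, factor(bin, levels = seq_along(mids)), sum)
    s[is.na(s)] <- 0
    sums <- sums + as.numeric(s)
    counts <- counts + tabulate(bin, length(mids))
  }
  has <- counts > 0
  if (sum(has) < 3) abort("fewer than 3 populated LD bins")
  fit_ld_decay(mids[has], (sums / pmax(counts, 1))[has], counts[has])
}

#' Divergence time from mean FST and effective population size
#'
#' Pure-drift, clean-split expectation: `t = -2 Ne ln(1 - FST)`
#' generations (reducing to `2 Ne FST` for small FST), converted to years
#' at 29 years per generation. Migration after the split inflates LD and
#' shared variance, so the estimate is approximate and downward-biased
#' under gene flow; it is labelled as such.
#'
#' @param fst_mean mean pairwise FST between the two populations, in
#'   `[0, 1)`.
#' @param ne_harmonic (harmonic-mean) effective population size to assume.
#' @return one-row tibble `fst_mean`, `ne`, `t_generations`, `t_years`,
#'   `note`.
#' @export
#' @examples
#' divergence_time(0.05, 1000)  # ~102.6 generations, ~2975 years
divergence_time <- function(fst_mean, ne_harmonic) {
  if (any(fst_mean < 0) || any(fst_mean >= 1)) {
    abort("fst_mean must be in [0, 1)")
  }
  stopifnot(all(ne_harmonic > 0))
  t_gen <- -2 * ne_harmonic * log(1 - fst_mean)
  tibble::tibble(
    fst_mean = fst_mean, ne = ne_harmonic,
    t_generations = t_gen,
    t_years = t_gen * GENERATION_YEARS,
    note = "approximate, downward-biased under migration"
  )
}
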