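#' Rank-based p-values for PBS
#'
#' Converts PBS values into empirical p-values: values are ranked in
#' decreasing order (rank 1 = largest) and divided by the number of
#' non-missing values; tied values share the mean rank of their block.
#'
#' @param pbs_values numeric vector (missing allowed).
#' @return numeric vector of rank p-values in `(0, 1]`, `NA` where PBS is
#'   missing.
#' @export
#' @examples
#' pbs_rank_p(c(5, 5, 1))  # 0.5, 0.5, 1
pbs_rank_p <- function(pbs_values) {
  if (!sum(is.finite(pbs_values))) abort("no finite PBS values")
  n <- sum(!is.na(pbs_values))
  rank(-pbs_values, ties.method = "average", na.last = "keep") / n
}

#' Fisher's method for combining p-values
#'
#' `chi2 = -2 * sum(log p)` on `2k` degrees of freedom, upper-tail
#' chi-square p-value. Zero p-values are clamped to `1e-300` with a
#' warning; any missing p yields a missing combination for that row.
#'
#' @param p numeric vector (one combination of `k` tests) or matrix /
#'   data frame (rows = items, columns = tests).
#' @return tibble with columns `chi2`, `df`, `p_combined` (one row per
#'   item).
#' @export
#' @examples
#' fisher_combine(c(0.01, 0.02, 0.03))
fisher_combine <- function(p) {
  pm <- if (is.null(dim(p))) matrix(as.numeric(p), nrow = 1) else as.matrix(p)
  if (any(pm <= 0, na.rm = TRUE)) {
    warn("p-value(s) of 0 clamped to 1e-300")
    pm[!is.na(pm) & pm <= 0] <- 1e-300
  }
  if (any(pm > 1, na.rm = TRUE)) abort("p-values must be in (0, 1]")
  k <- ncol(pm)
  chi2 <- -2 * rowSums(log(pm))
  tibble::tibble(chi2 = chi2, df = 2L * k,
                 p_combined = pchisq(chi2, 2 * k, lower.tail = FALSE))
}

#' Bonferroni significance flag
#'
#' Strict inequality, as in `p < alpha / n_tests`.
#'
#' @param p_combined numeric vector of p-values.
#' @param alpha family-wise error rate (default 0.01).
#' @param n_tests number of tests; defaults to the number of non-missing
#'   p-values.
#' @return logical vector; `FALSE` for missing p.
#' @export
bonferroni_flag <- function(p_combined, alpha = 0.01,
                            n_tests = sum(!is.na(p_combined))) {
  if (n_tests == 0) abort("n_tests is 0: nothing was tested")
  !is.na(p_combined) & p_combined < alpha / n_tests
}

#' Combine the three selection statistics per variant
#'
#' Joins the Spearman, mixed-model and PBS scans on variant id, converts
#' PBS to rank p-values, combines the three p-values by Fisher's method
#' for every variant that has all three, and applies the Bonferroni flag
#' at `alpha / N` with `N` the number of variants combined. The three
#' tests are not independent; no dependence correction is applied, so the
#' combined p is a ranking device rather than a type-1-error rate.
#'
#' @param spearman,lmm,pbs outputs of [spearman_altitude_scan()],
#'   [lmm_assoc_scan()] and [pbs_scan()].
#' @param alpha family-wise rate for the Bonferroni flag (default 0.01).
#' @return tibble `vid`, `chrom`, `pos`, `p_spearman`, `p_lmm`,
#'   `p_rank_pbs`, `chi2`, `p_combined`, `sig`.
#' @export
combine_evidence <- function(spearman, lmm, pbs, alpha = 0.01) {
  tab <- spearman |>
    dplyr::select("vid", "chrom", "pos", "p_spearman") |>
    dplyr::inner_join(dplyr::select(lmm, "vid", "p_lmm"), by = "vid") |>
    dplyr::mutate(p_rank_pbs = pbs_rank_p(
      pbs$pbs[match(.data$vid, pbs$vid)]))
  fish <- fisher_combine(as.matrix(tab[, c("p_spearman", "p_lmm",
                                           "p_rank_pbs")]))
  tab$chi2 <- fish$chi2
  tab$p_combined <- fish$p_combined
  tab$sig <- bonferroni_flag(tab$p_combined, alpha = alpha)
  attr(tab, "n_tests") <- sum(!is.na(tab$p_combined))
  tab
}

#' Overlap of significant variant sets across methods
#'
#' @param sig_sets named list of character vectors of variant ids.
#' @return list with `membership` (tibble: vid + one logical column per
#'   method + `in_all`), `all_sets` (ids present in every set) and
#'   `pairwise` (tibble of pairwise intersection counts).
#' @export
collate_overlap <- function(sig_sets) {
  if (length(sig_sets) < 2) abort("need at least 2 sets")
  if (is.null(names(sig_sets)) || any(!nzchar(names(sig_sets)))) {
    abort("sig_sets must be named")
  }
  vids <- unique(unlist(sig_sets))
  membership <- tibble::tibble(vid = vids)
  for (nm in names(sig_sets)) membership[[nm]] <- vids %in% sig_sets[[nm]]
  membership$in_all <- rowSums(as.matrix(
    membership[names(sig_sets)])) == length(sig_sets)
  pairs <- utils::combn(names(sig_sets), 2)
  pairwise <- tibble::tibble(
    set1 = pairs[1, ], set2 = pairs[2, ],
    n_overlap = apply(pairs, 2, function(p)
      length(intersect(sig_sets[[p[1]]], sig_sets[[p[2]]])))
  )
  list(membership = membership,
       all_sets = vids[membership$in_all],
       pairwise = pairwise)
}

#' Cluster significant SNPs into candidate regions
#'
#' Single-linkage chaining along each chromosome: consecutive significant
#' SNPs whose gap is at most `max_gap_bp` join one region. Every region is
#' reported with its span (1-based inclusive, min/max member positions),
#' member count and top SNP (minimum combined p, ties broken by smaller
#' position); the `kept` column marks regions with at least `min_snps`
#' members, singletons being reported but not kept by default.
#'
#' @param sig_variants tibble with columns `chrom`, `pos`, `vid` and
#'   optionally `p_combined`, one row per significant SNP.
#' @param max_gap_bp maximum gap joining two SNPs into a region
#'   (default 500,000).
#' @param min_snps minimum members for a kept region (default 2).
#' @return tibble `chrom`, `start`, `end`, `n_snps`, `top_vid`, `top_p`,
#'   `kept`, `vids` (list column of member ids).
#' @export
cluster_regions <- function(sig_variants, max_gap_bp = 500000,
                            min_snps = 2) {
  sv <- dplyr::arrange(tibble::as_tibble(sig_variants),
                       .data$chrom, .data$pos)
  if (!"p_combined" %in% names(sv)) sv$p_combined <- NA_real_
  if (!nrow(sv)) {
    return(tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0), n_snps = integer(0),
                          top_vid = character(0), top_p = numeric(0),
                          kept = logical(0), vids = list()))
  }
  new_region <- c(TRUE, diff(sv$pos) > max_gap_bp |
                    sv$chrom[-1] != sv$chrom[-nrow(sv)])
  sv$region <- cumsum(new_region)
  sv |>
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom),
      start = min(.data$pos), end = max(.data$pos),
      n_snps = dplyr::n(),
      top_vid = .data$vid[order(.data$p_combined, .data$pos)][1],
      top_p = suppressWarnings(min(.data$p_combined, na.rm = TRUE)),
      vids = list(.data$vid),
      .by = "region"
    ) |>
    dplyr::mutate(kept = .data$n_snps >= min_snps,
                  top_p = ifelse(is.finite(.data$top_p), .data$top_p,
                                 NA_real_)) |>
    dplyr::select("chrom", "start", "end", "n_snps", "top_vid", "top_p",
                  "kept", "vids")
}
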