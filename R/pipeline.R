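#' Full altitude-adaptation selection scan
#'
#' Runs the three per-SNP selection statistics on one panel and combines
#' them: (1) Spearman correlation of per-population derived allele
#' frequency with altitude over the study (non-external) populations;
#' (2) kinship-corrected mixed-model association of altitude on dosage
#' over the study samples; (3) the Population Branch Statistic with the
#' high-altitude populations pooled as the focal group against the close
#' lowland reference and the outgroup. Per-variant evidence is merged by
#' Fisher's method on (p_spearman, p_lmm, rank-p of PBS) with a Bonferroni
#' flag at `0.01 / N`.
#'
#' @param panel a QC'd [genotype_panel()].
#' @param populations a [population_panel()]; populations with region
#'   `"external"` are excluded from the Spearman/LMM stages.
#' @param ref_c,ref_o population codes of the closest lowland reference
#'   and the outgroup reference for PBS.
#' @param group_h population codes pooled as the PBS focal group; default:
#'   all non-external populations flagged `high_altitude` (>= 2,500 m).
#' @param pbs_percentile empirical PBS percentile (default 99.99).
#' @param alpha_combined Bonferroni family-wise rate on the combined p
#'   (default 0.01).
#' @return list with elements `spearman`, `lmm`, `pbs`, `combined` (the
#'   per-variant tibbles) and `null_fit`.
#' @export
altitude_scan <- function(panel, populations, ref_c = "EAS",
                          ref_o = "EUR", group_h = NULL,
                          pbs_percentile = 99.99, alpha_combined = 0.01) {
  ext <- populations$code[!is.na(populations$region) &
                            populations$region == "external"]
  study_pops <- setdiff(intersect(populations$code,
                                  unique(panel$samples$population)), ext)
  group_h <- group_h %||% intersect(
    populations$code[populations$high_altitude], study_pops)
  if (!length(group_h)) abort("no high-altitude populations to pool for PBS")

  freqs <- allele_frequencies(panel, study_pops)
  sp <- spearman_altitude_scan(freqs, populations)

  study_panel <- subset_panel(panel,
                              samples = panel$samples$population %in%
                                study_pops)
  k <- kinship_grm(study_panel)
  alt <- sample_altitudes(study_panel, populations)
  null_fit <- lmm_fit_null(alt, k)
  lm_tab <- lmm_assoc_scan(study_panel, null_fit)

  pbs_tab <- pbs_scan(panel, group_h, ref_c, ref_o,
                      percentile = pbs_percentile)

  combined <- combine_evidence(sp, lm_tab, pbs_tab, alpha = alpha_combined)
  list(spearman = sp, lmm = lm_tab, pbs = pbs_tab, combined = combined,
       null_fit = null_fit)
}

#' Bayes-factor interpretation categories for environmental association
#'
#' Conventional Jeffreys-scale cut-offs used to grade Bayes factors from
#' Bayesian genotype-environment association methods. Recorded as
#' configuration constants only; no Bayes-factor computation is performed
#' by this package.
#'
#' @format a tibble with columns `category`, `bf_min`, `bf_max`,
#'   `log10_bf_min`, `log10_bf_max`.
#' @export
bayenv_bf_categories <- tibble::tibble(
  category = c("substantial", "strong", "decisive"),
  bf_min = c(3.2, 10, 100),
  bf_max = c(10, 100, Inf),
  log10_bf_min = c(0.5, 1, 2),
  log10_bf_max = c(1, 2, Inf)
)
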