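#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the null mixed-model fit
#'
#' @param x an [lmm_fit_null()] object.
#' @param ... unused.
#' @return tibble of variance-component estimates.
#' @export
tidy.lmm_null_fit <- function(x, ...) {
  tibble::tibble(
    term = c("sigma_g2", "sigma_e2", "delta", "h2"),
    estimate = c(x$sigma_g2, x$sigma_e2, x$delta, x$h2)
  )
}

#' @rdname tidy.lmm_null_fit
#' @return for `glance`: one-row tibble with fit summary.
#' @export
glance.lmm_null_fit <- function(x, ...) {
  tibble::tibble(n = x$n, sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2,
                 h2 = x$h2, reml_loglik = x$reml)
}

#' Tidy an LD-decay Ne trajectory
#'
#' @param x an `ne_trajectory` from [fit_ld_decay()] / [ne_from_ld()].
#' @param ... unused.
#' @return for `tidy`: the per-bin trajectory tibble; for `glance`: a
#'   one-row summary with the fitted decay parameters and Ne estimates.
#' @export
tidy.ne_trajectory <- function(x, ...) x$bins

#' @rdname tidy.ne_trajectory
#' @export
glance.ne_trajectory <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, beta = x$beta,
                 ne_long_term = x$ne_long_term,
                 ne_harmonic = x$ne_harmonic,
                 n_bins = nrow(x$bins), rss = x$rss,
                 generation_years = x$generation_years)
}
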