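#' Manhattan plot of combined selection evidence
#'
#' @param combined output of [combine_evidence()].
#' @param highlight optional variant ids to mark (e.g. planted or candidate
#'   loci).
#' @return a ggplot object.
#' @export
plot_manhattan <- function(combined, highlight = NULL) {
  df <- dplyr::mutate(combined,
                      chrom = factor(.data$chrom, unique(.data$chrom)),
                      logp = -log10(.data$p_combined))
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$pos, .data$logp)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chrom),
                        size = 0.4, show.legend = FALSE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x", switch = "x") +
    ggplot2::labs(x = "chromosome", y = expression(-log[10](p[combined]))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(0.1, "lines"))
  n <- attr(combined, "n_tests")
  if (!is.null(n) && n > 0) {
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(0.01 / n),
                                   linetype = "dashed")
  }
  if (!is.null(highlight)) {
    gg <- gg + ggplot2::geom_point(
      data = df[df$vid %in% highlight, ], colour = "red", size = 1)
  }
  gg
}

#' Plot an LD-decay Ne trajectory
#'
#' @param object an `ne_trajectory`.
#' @param ... unused.
#' @return a ggplot object: per-bin Ne_t against time (generations ago),
#'   with the harmonic-mean Ne as a dashed line.
#' @export
autoplot.ne_trajectory <- function(object, ...) {
  df <- object$bins[!is.na(object$bins$ne_t) & object$bins$ne_t > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$t_generations, .data$ne_t)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$ne_harmonic,
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "generations ago (t = 1/2c)",
                  y = expression(N[e](t)),
                  title = sprintf("harmonic-mean Ne = %.0f",
                                  object$ne_harmonic)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' QQ plot of association p-values with genomic inflation factor
#'
#' @param p numeric vector of p-values.
#' @return a ggplot object annotated with lambda_GC.
#' @export
plot_qq <- function(p) {
  p <- sort(p[!is.na(p)])
  lambda <- genomic_inflation(p)
  df <- tibble::tibble(expected = -log10(stats::ppoints(length(p))),
                       observed = -log10(p))
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = expression(expected ~ -log[10](p)),
                  y = expression(observed ~ -log[10](p)),
                  title = sprintf("lambda[GC] = %.3f", lambda)) +
    ggplot2::theme_minimal()
}

#' Genomic inflation factor of a p-value vector
#'
#' `lambda_GC`: the median association chi-square (1 df) divided by its
#' null expectation 0.455.
#'
#' @param p numeric p-values.
#' @return lambda_GC.
#' @export
genomic_inflation <- function(p) {
  p <- p[!is.na(p)]
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}
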