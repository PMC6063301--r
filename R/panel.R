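#' Genotype panel container
#'
#' A `genotype_panel` bundles a diploid dosage matrix with its variant and
#' sample tables. Dosages count copies of `allele_b` (the ALT/A2 allele),
#' taking values 0, 1, 2 or `NA` for missing. Rows of the matrix are samples,
#' columns are variants.
#'
#' @param genotypes integer matrix, samples x variants, values in
#'   `{0, 1, 2, NA}`.
#' @param variants tibble with columns `chrom`, `pos` (1-based), `vid`,
#'   `allele_a`, `allele_b`, and optionally `ancestral` (one of `"a"`, `"b"`,
#'   `"unknown"`) and `cm` (genetic-map position in centimorgans).
#' @param samples tibble with columns `sample_id` and `population`.
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `genotypes`, `variants`, `samples`.
#' @export
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 0L), nrow = 2)
#' v <- tibble::tibble(chrom = "1", pos = c(100L, 200L), vid = c("v1", "v2"),
#'                     allele_a = "A", allele_b = "G")
#' s <- tibble::tibble(sample_id = c("s1", "s2"), population = "POP")
#' genotype_panel(g, v, s)
genotype_panel <- function(genotypes, variants, samples) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  variants <- tibble::as_tibble(variants)
  samples <- tibble::as_tibble(samples)
  if (!"ancestral" %in% names(variants)) variants$ancestral <- "unknown"
  if (!all(variants$ancestral %in% c("a", "b", "unknown"))) {
    abort("`ancestral` must be one of \"a\", \"b\", \"unknown\".")
  }
  validate_panel(structure(
    list(genotypes = genotypes, variants = variants, samples = samples),
    class = "genotype_panel"
  ))
}

validate_panel <- function(x) {
  stopifnot(inherits(x, "genotype_panel"))
  if (nrow(x$genotypes) != nrow(x$samples)) {
    abort(sprintf("genotype matrix has %d rows but %d samples",
                  nrow(x$genotypes), nrow(x$samples)))
  }
  if (ncol(x$genotypes) != nrow(x$variants)) {
    abort(sprintf("genotype matrix has %d columns but %d variants",
                  ncol(x$genotypes), nrow(x$variants)))
  }
  need <- c("chrom", "pos", "vid", "allele_a", "allele_b")
  miss <- setdiff(need, names(x$variants))
  if (length(miss)) abort(paste("variant table missing columns:",
                                paste(miss, collapse = ", ")))
  if (nrow(x$variants)) {
    if (any(x$variants$pos < 1)) abort("variant positions must be >= 1")
    same <- x$variants$allele_a == x$variants$allele_b
    if (any(same)) abort("allele_a and allele_b must differ")
  }
  if (anyDuplicated(x$samples$sample_id)) abort("duplicate sample ids")
  bad <- x$genotypes[!is.na(x$genotypes) &
                       !(x$genotypes %in% c(0L, 1L, 2L))]
  if (length(bad)) abort("genotype dosages must be 0, 1, 2 or NA")
  x
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d variants\n",
              nrow(x$samples), nrow(x$variants)))
  cat(sprintf("  populations: %s\n",
              paste(unique(x$samples$population), collapse = ", ")))
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$genotypes)

#' Number of samples / variants in a panel
#' @param panel a [genotype_panel()].
#' @return integer count.
#' @export
n_samples <- function(panel) nrow(panel$samples)

#' @rdname n_samples
#' @export
n_variants <- function(panel) nrow(panel$variants)

#' Subset a genotype panel
#'
#' @param panel a [genotype_panel()].
#' @param samples,variants logical, integer or character index into the
#'   sample / variant tables (characters match `sample_id` / `vid`).
#' @return a new `genotype_panel`.
#' @export
subset_panel <- function(panel, samples = NULL, variants = NULL) {
  si <- seq_len(n_samples(panel))
  vi <- seq_len(n_variants(panel))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) {
      match(samples, panel$samples$sample_id)
    } else si[samples]
    if (anyNA(si)) abort("unknown sample id in subset")
  }
  if (!is.null(variants)) {
    vi <- if (is.character(variants)) {
      match(variants, panel$variants$vid)
    } else vi[variants]
    if (anyNA(vi)) abort("unknown variant id in subset")
  }
  genotype_panel(panel$genotypes[si, vi, drop = FALSE],
                 panel$variants[vi, , drop = FALSE],
                 panel$samples[si, , drop = FALSE])
}

#' Samples belonging to given populations
#' @param panel a [genotype_panel()].
#' @param populations character vector of population codes.
#' @return integer row indices into the sample table.
#' @export
population_samples <- function(panel, populations) {
  which(panel$samples$population %in% populations)
}
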