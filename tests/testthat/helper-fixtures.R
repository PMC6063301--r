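# Small panel builders used across test files.

make_panel <- function(geno, chrom = "1", pos = NULL, pops = "POP",
                       ancestral = "a", cm = NULL) {
  geno <- as.matrix(geno)
  m <- ncol(geno); n <- nrow(geno)
  pos <- pos %||% seq(1000L, by = 1000L, length.out = m)
  v <- tibble::tibble(
    chrom = rep_len(as.character(chrom), m), pos = as.integer(pos),
    vid = paste0("v", seq_len(m)),
    allele_a = "A", allele_b = "G",
    ancestral = rep_len(ancestral, m)
  )
  if (!is.null(cm)) v$cm <- cm
  s <- tibble::tibble(sample_id = paste0("s", seq_len(n)),
                      population = rep_len(pops, n))
  genotype_panel(geno, v, s)
}

make_pops <- function(codes, altitude_m, region = "Nepal") {
  population_panel(tibble::tibble(
    sample_id = paste0(codes, "_x"), population = codes,
    altitude_m = altitude_m, region = rep_len(region, length(codes)),
    language = NA_character_
  ))
}

# genotype draws in exact HWE-expected proportions are not needed often;
# this draws binomial genotypes at frequency p for n samples, m variants
hwe_genotypes <- function(n, m, p) {
  matrix(rbinom(n * m, 2L, rep_len(p, m)[rep(seq_len(m), each = n)]),
         nrow = n)
}
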