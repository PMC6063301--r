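#' Simulation configuration for structured genotype panels
#'
#' Describes a Balding-Nichols style panel: a set of populations drifting
#' independently from a shared ancestral pool, each with its own drift
#' coefficient `F` and residence altitude, plus an optional minority of
#' loci whose derived-allele frequency increases with altitude. Defaults
#' emulate a Himalayan-scale study: 20 populations of 10-20 samples at
#' altitudes spanning 100-4,500 m, drift F in [0.01, 0.2], 20,000 variants
#' of which 0.5% are altitude-selected with slope 0.15 per km, and two
#' larger low-altitude external reference populations (an East-Asian-like
#' close reference `EAS` and a European-like outgroup `EUR`).
#'
#' @param n_populations number of study populations.
#' @param n_samples integer vector (recycled) of samples per population.
#' @param f_pop drift coefficient(s) in (0, 1), recycled; if `NULL`, drawn
#'   uniformly on `f_range` at simulation time.
#' @param f_range range for random drift coefficients.
#' @param altitude_m per-population altitudes (metres); if `NULL`, drawn
#'   uniformly on `altitude_range` at simulation time.
#' @param altitude_range altitude range (metres).
#' @param n_variants number of variants.
#' @param fraction_selected fraction of loci under altitude-coupled
#'   selection, in `[0, 1)`.
#' @param selection_slope derived-frequency shift per km of altitude.
#' @param selection_cluster_size planted loci are placed in runs of this
#'   many adjacent variants, mimicking the footprint of a selective sweep.
#' @param freq_range ancestral derived-allele frequency range (uniform).
#' @param selected_freq_range ancestral frequency range for loci placed
#'   under selection: adaptive derived alleles are modelled as ancestrally
#'   rare, rising with altitude.
#' @param n_chromosomes variants are spread evenly over this many
#'   chromosomes, positions spaced 2-4 kb, 1 cM/Mb map.
#' @param reference_pops logical: append the `EAS`/`EUR` external
#'   references (drift 0.02 and 0.16, 30 samples each, low altitude).
#' @param seed integer seed making the whole panel reproducible.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_populations = 20,
                       n_samples = NULL,
                       f_pop = NULL,
                       f_range = c(0.01, 0.2),
                       altitude_m = NULL,
                       altitude_range = c(100, 4500),
                       n_variants = 20000,
                       fraction_selected = 0.005,
                       selection_slope = 0.15,
                       selection_cluster_size = 5,
                       freq_range = c(0.05, 0.95),
                       selected_freq_range = c(0.05, 0.3),
                       n_chromosomes = 20,
                       reference_pops = TRUE,
                       seed = 1L) {
  stopifnot(fraction_selected >= 0, fraction_selected < 1,
            is.null(f_pop) || all(f_pop > 0 & f_pop < 1))
  structure(list(
    n_populations = n_populations, n_samples = n_samples, f_pop = f_pop,
    f_range = f_range, altitude_m = altitude_m,
    altitude_range = altitude_range, n_variants = n_variants,
    fraction_selected = fraction_selected,
    selection_slope = selection_slope,
    selection_cluster_size = selection_cluster_size,
    freq_range = freq_range, selected_freq_range = selected_freq_range,
    n_chromosomes = n_chromosomes,
    reference_pops = reference_pops, seed = as.integer(seed)
  ), class = "sim_config")
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

sim_variant_table <- function(n_variants, n_chromosomes, seed_offset = 0) {
  per_chrom <- ceiling(n_variants / n_chromosomes)
  chrom <- rep(seq_len(n_chromosomes), each = per_chrom)[seq_len(n_variants)]
  gaps <- sample(2000:4000, n_variants, replace = TRUE)
  pos <- unlist(lapply(split(gaps, chrom), cumsum), use.names = FALSE)
  tibble::tibble(
    chrom = as.character(chrom), pos = as.integer(pos),
    vid = sprintf("snp%06d", seq_len(n_variants)),
    allele_a = "A", allele_b = "G",
    ancestral = "a",          # allele_b is the derived allele
    cm = pos * 1e-6           # 1 cM/Mb constant map
  )
}

draw_bn_genotypes <- function(pop_freq, n_per_pop) {
  # pop_freq: n_pops x m derived-allele frequencies
  m <- ncol(pop_freq)
  do.call(rbind, lapply(seq_len(nrow(pop_freq)), function(k) {
    matrix(rbinom(n_per_pop[k] * m, 2L,
                  rep(pop_freq[k, ], each = n_per_pop[k])),
           nrow = n_per_pop[k])
  }))
}

#' Simulate a structured panel under the Balding-Nichols model
#'
#' For each variant an ancestral derived-allele frequency `p` is drawn,
#' and each population `k` receives a frequency
#' `p_k ~ Beta(p(1-F_k)/F_k, (1-p)(1-F_k)/F_k)`, so that
#' `E[p_k] = p` and `Var[p_k] = p(1-p) F_k`. Diploid genotypes are then
#' binomial draws `Bin(2, p_k)`. If the configuration requests selected
#' loci, [plant_altitude_selection()] is applied to clustered runs of
#' adjacent variants.
#'
#' @param config a [sim_config()].
#' @return list with elements `panel` (a [genotype_panel()]),
#'   `populations` (a [population_panel()]) and `truth` (list with
#'   `ancestral_freq`, `pop_freq` matrix, `selected` tibble of planted
#'   loci).
#' @export
simulate_balding_nichols <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_if(config$seed, {
    npop <- config$n_populations
    f <- config$f_pop %||% runif(npop, config$f_range[1], config$f_range[2])
    f <- rep_len(f, npop)
    alt <- config$altitude_m %||%
      runif(npop, config$altitude_range[1], config$altitude_range[2])
    alt <- round(rep_len(alt, npop))
    nsamp <- config$n_samples %||% sample(10:20, npop, replace = TRUE)
    nsamp <- rep_len(nsamp, npop)
    codes <- sprintf("P%02d", seq_len(npop))
    region <- rep("Nepal", npop)
    if (config$reference_pops) {
      codes <- c(codes, "EAS", "EUR")
      f <- c(f, 0.02, 0.16)
      alt <- c(alt, 100, 200)
      nsamp <- c(nsamp, 30L, 30L)
      region <- c(region, "external", "external")
      npop <- npop + 2L
    }
    m <- config$n_variants
    variants <- sim_variant_table(m, config$n_chromosomes)
    p <- runif(m, config$freq_range[1], config$freq_range[2])
    pop_freq <- matrix(NA_real_, nrow = npop, ncol = m,
                       dimnames = list(codes, variants$vid))
    for (k in seq_len(npop)) {
      shape_scale <- (1 - f[k]) / f[k]
      pop_freq[k, ] <- rbeta(m, p * shape_scale, (1 - p) * shape_scale)
    }
    geno <- draw_bn_genotypes(pop_freq, nsamp)
    samples <- tibble::tibble(
      sample_id = sprintf("%s_%03d", rep(codes, nsamp),
                          unlist(lapply(nsamp, seq_len))),
      population = rep(codes, nsamp)
    )
    panel <- genotype_panel(geno, variants, samples)
    populations <- population_panel(tibble::tibble(
      sample_id = samples$sample_id, population = samples$population,
      altitude_m = rep(alt, nsamp), region = rep(region, nsamp),
      language = NA_character_
    ))
    truth <- list(ancestral_freq = setNames(p, variants$vid),
                  pop_freq = pop_freq,
                  selected = tibble::tibble(vid = character(0),
                                            slope = numeric(0)))
    out <- list(panel = panel, populations = populations, truth = truth)
    if (config$fraction_selected > 0) {
      n_sel <- round(config$fraction_selected * m)
      k_clust <- max(1L, round(n_sel / config$selection_cluster_size))
      # one clustered run of adjacent variants per chromosome slot
      starts <- sort(sample(seq_len(m - config$selection_cluster_size),
                            k_clust))
      loci <- unique(unlist(lapply(starts, function(s)
        seq.int(s, length.out = config$selection_cluster_size))))
      # adaptive derived alleles start ancestrally rare: redraw the base
      # frequency of selected loci from the low range, then re-drift
      p_sel <- runif(length(loci), config$selected_freq_range[1],
                     config$selected_freq_range[2])
      truth$ancestral_freq[loci] <- p_sel
      for (k in seq_len(npop)) {
        shape_scale <- (1 - f[k]) / f[k]
        truth$pop_freq[k, loci] <- rbeta(length(loci), p_sel * shape_scale,
                                         (1 - p_sel) * shape_scale)
      }
      out <- plant_altitude_selection(
        panel, truth, populations,
        loci = variants$vid[loci], slope = config$selection_slope,
        seed = NULL)
      out$populations <- populations
    }
    out
  })
}

#' Plant altitude-coupled selection at chosen loci
#'
#' Shifts each population's derived-allele frequency at the chosen loci by
#' `slope` per km of residence altitude (clamped to `[0.01, 0.99]`) and
#' redraws the genotypes at those loci only; all other loci are untouched.
#'
#' @param panel a [genotype_panel()].
#' @param truth truth list from [simulate_balding_nichols()] (holds the
#'   per-population frequency matrix to shift).
#' @param populations a [population_panel()] supplying altitudes.
#' @param loci variant ids to place under selection.
#' @param slope derived-frequency shift per km of altitude.
#' @param seed optional seed for the genotype redraw.
#' @return list `panel`, `truth` with the `selected` table filled in.
#' @export
plant_altitude_selection <- function(panel, truth, populations, loci,
                                     slope, seed = NULL) {
  vi <- match(loci, panel$variants$vid)
  if (anyNA(vi)) abort("unknown locus id in `loci`")
  with_seed_if(seed, {
    alt_km <- populations$altitude_m[
      match(rownames(truth$pop_freq), populations$code)] / 1000
    shifted <- truth$pop_freq[, vi, drop = FALSE] + slope * alt_km
    shifted <- pmin(pmax(shifted, 0.01), 0.99)
    if (all(shifted == 0.01) || all(shifted == 0.99)) {
      warn("selection slope drives all planted loci to fixation bounds")
    }
    truth$pop_freq[, vi] <- shifted
    pop_of <- match(panel$samples$population, rownames(truth$pop_freq))
    for (j in seq_along(vi)) {
      panel$genotypes[, vi[j]] <-
        rbinom(n_samples(panel), 2L, shifted[pop_of, j])
    }
    truth$selected <- dplyr::bind_rows(
      truth$selected,
      tibble::tibble(vid = loci, slope = slope))
    list(panel = panel, truth = truth)
  })
}

#' Simulate an admixed population from two source frequency vectors
#'
#' Admixed derived-allele frequencies are `lambda * p_A + (1-lambda) * p_B`;
#' genotypes are binomial draws from the mixed frequencies.
#'
#' @param freqs_a,freqs_b per-variant derived-allele frequencies of the two
#'   sources.
#' @param lambda admixture proportion from source A, in `[0, 1]`.
#' @param n_samples number of diploid samples to draw.
#' @param seed optional seed.
#' @return list with `genotypes` (samples x variants) and `freq` (the mixed
#'   frequency vector).
#' @export
simulate_admixed_population <- function(freqs_a, freqs_b, lambda,
                                        n_samples, seed = NULL) {
  stopifnot(lambda >= 0, lambda <= 1, length(freqs_a) == length(freqs_b))
  with_seed_if(seed, {
    fmix <- lambda * freqs_a + (1 - lambda) * freqs_b
    g <- matrix(rbinom(n_samples * length(fmix), 2L,
                       rep(fmix, each = n_samples)), nrow = n_samples)
    list(genotypes = g, freq = fmix)
  })
}

#' Simulate a diploid panel with haplotype-block LD
#'
#' Each haplotype is a mosaic of `n_founders` founder haplotypes: a Markov
#' path over founder indices with switch probability per inter-variant
#' interval equal to the genetic distance in Morgans (1 cM/Mb constant map
#' unless `cm` positions are supplied). Small founder pools give strong,
#' slowly decaying LD (small effective population size); large pools give
#' fast decay. Diploids pair consecutive haplotypes.
#'
#' @param n_samples number of diploid samples.
#' @param n_variants number of variants.
#' @param n_founders founder-haplotype pool size (>= 2).
#' @param n_chromosomes chromosomes to spread variants over.
#' @param switch_scale multiplier on inter-variant switch probabilities
#'   (1 = use map distance as is).
#' @param freq_range founder allele-frequency range.
#' @param population population code for the sample table.
#' @param seed optional seed.
#' @return a [genotype_panel()]; founder haplotypes in attribute
#'   `"founders"`.
#' @export
simulate_haplotype_mosaic <- function(n_samples, n_variants,
                                      n_founders = 20, n_chromosomes = 2,
                                      switch_scale = 1,
                                      freq_range = c(0.1, 0.9),
                                      population = "SIM", seed = NULL) {
  stopifnot(n_founders >= 2)
  with_seed_if(seed, {
    variants <- sim_variant_table(n_variants, n_chromosomes)
    p <- runif(n_variants, freq_range[1], freq_range[2])
    founders <- matrix(rbinom(n_founders * n_variants, 1L,
                              rep(p, each = n_founders)),
                       nrow = n_founders)
    # switch probability per interval; zero across chromosome boundaries
    d_morgans <- diff(variants$cm) / 100
    new_chrom <- diff(as.integer(factor(variants$chrom,
                                        unique(variants$chrom)))) != 0
    sw <- pmin(pmax(d_morgans * switch_scale, 0), 1)
    sw[new_chrom] <- 1  # independent founder draw on a new chromosome
    n_hap <- 2L * n_samples
    haps <- matrix(0L, nrow = n_hap, ncol = n_variants)
    for (h in seq_len(n_hap)) {
      switches <- runif(n_variants - 1) < sw
      seg <- cumsum(c(TRUE, switches))          # segment id per variant
      draws <- sample.int(n_founders, seg[n_variants], replace = TRUE)
      idx <- draws[seg]
      haps[h, ] <- founders[cbind(idx, seq_len(n_variants))]
    }
    geno <- haps[seq(1, n_hap, by = 2), , drop = FALSE] +
      haps[seq(2, n_hap, by = 2), , drop = FALSE]
    panel <- genotype_panel(
      geno, variants,
      tibble::tibble(sample_id = sprintf("%s_%03d", population,
                                         seq_len(n_samples)),
                     population = population))
    attr(panel, "founders") <- founders
    panel
  })
}

#' Plant a run of homozygosity in one sample
#'
#' Within the chosen interval the sample's heterozygous genotypes are
#' resolved to a homozygote by copying one allele chosen at random (one
#' haplotype is duplicated); homozygous and missing calls are left as they
#' are, and everything outside the interval is untouched.
#'
#' @param panel a [genotype_panel()].
#' @param sample sample id.
#' @param chrom chromosome label.
#' @param start_idx 1-based index of the first variant of the run *within
#'   that chromosome's variants*.
#' @param n_snps run length in variants; 0 leaves the panel unchanged.
#' @param seed optional seed for the haplotype choice.
#' @return the modified [genotype_panel()]; planted intervals accumulate in
#'   attribute `"planted_roh"` (tibble `sample`, `chrom`, `start_idx`,
#'   `end_idx`, `start_pos`, `end_pos`).
#' @export
plant_roh <- function(panel, sample, chrom, start_idx, n_snps,
                      seed = NULL) {
  prev <- attr(panel, "planted_roh") %||%
    tibble::tibble(sample = character(0), chrom = character(0),
                   start_idx = integer(0), end_idx = integer(0),
                   start_pos = integer(0), end_pos = integer(0))
  if (n_snps == 0) return(panel)
  si <- match(sample, panel$samples$sample_id)
  if (is.na(si)) abort("unknown sample id")
  on_chrom <- which(panel$variants$chrom == as.character(chrom))
  if (start_idx < 1 || start_idx + n_snps - 1 > length(on_chrom)) {
    abort("ROH interval outside the chromosome's variant range")
  }
  end_idx <- start_idx + n_snps - 1L
  clash <- prev$sample == sample & prev$chrom == as.character(chrom) &
    prev$start_idx <= end_idx & prev$end_idx >= start_idx
  if (any(clash)) abort("overlapping planted ROH intervals for one sample")
  cols <- on_chrom[start_idx:end_idx]
  with_seed_if(seed, {
    g <- panel$genotypes[si, cols]
    het <- !is.na(g) & g == 1L
    g[het] <- 2L * rbinom(sum(het), 1L, 0.5)
    panel$genotypes[si, cols] <- g
  })
  attr(panel, "planted_roh") <- dplyr::bind_rows(prev, tibble::tibble(
    sample = sample, chrom = as.character(chrom),
    start_idx = as.integer(start_idx), end_idx = as.integer(end_idx),
    start_pos = panel$variants$pos[cols[1]],
    end_pos = panel$variants$pos[cols[length(cols)]]
  ))
  panel
}

#' Generate LD-decay bins from the hyperbolic decay model
#'
#' Produces adjusted-r-squared means on a grid of recombination distances
#' under `r2_adj(c) = 1/(alpha + 4 Ne c)` plus Gaussian noise truncated at
#' zero — the generative counterpart of [ne_from_ld()].
#'
#' @param ne effective population size (> 0).
#' @param alpha intercept of the decay model.
#' @param c_bins recombination distances in Morgans, ascending.
#' @param n_chrom chromosome sample size the r-squared values are notionally
#'   adjusted for (recorded, not used).
#' @param noise_sd standard deviation of additive noise (0 = noiseless).
#' @param seed optional seed.
#' @return tibble with columns `c`, `r2_adj`, `n_chrom`.
#' @export
simulate_ld_decay_bins <- function(ne, alpha = 1, c_bins, n_chrom = 100,
                                   noise_sd = 0, seed = NULL) {
  stopifnot(ne > 0, all(diff(c_bins) > 0))
  with_seed_if(seed, {
    y <- 1 / (alpha + 4 * ne * c_bins)
    if (noise_sd > 0) y <- pmax(y + rnorm(length(y), 0, noise_sd), 0)
    tibble::tibble(c = c_bins, r2_adj = y, n_chrom = n_chrom)
  })
}
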