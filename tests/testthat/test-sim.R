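test_that("Balding-Nichols frequencies have the drift-model moments", {
  cfg <- sim_config(n_populations = 3, n_samples = 10,
                    f_pop = c(0.001, 0.2, 0.5),
                    altitude_m = c(100, 2000, 4000),
                    n_variants = 5000, fraction_selected = 0,
                    freq_range = c(0.5, 0.5),   # fix p to isolate moments
                    reference_pops = FALSE, seed = 21)
  sim <- simulate_balding_nichols(cfg)
  pf <- sim$truth$pop_freq
  p <- 0.5
  for (k in 1:3) {
    f <- cfg$f_pop[k]
    expect_equal(mean(pf[k, ]), p, tolerance = 0.02)
    expect_equal(var(pf[k, ]), p * (1 - p) * f, tolerance = 0.2)
  }
  # F = 0.5, p = 0.5: distribution symmetric about 0.5 (sign test)
  dev <- pf[3, ] - 0.5
  st <- stats::binom.test(sum(dev > 0), sum(dev != 0))
  expect_gt(st$p.value, 0.01)
  # tiny F: frequencies hug the ancestral value
  expect_lt(mean(abs(pf[1, ] - 0.5)), 0.05)
})

test_that("generators are seed-deterministic and truth is consistent", {
  cfg <- sim_config(n_populations = 5, n_variants = 400,
                    n_chromosomes = 2, seed = 99)
  a <- simulate_balding_nichols(cfg)
  b <- simulate_balding_nichols(cfg)
  expect_identical(a$panel$genotypes, b$panel$genotypes)
  expect_identical(a$truth$pop_freq, b$truth$pop_freq)
  expect_true(all(a$truth$selected$vid %in% a$panel$variants$vid))

  m1 <- simulate_haplotype_mosaic(20, 150, seed = 4)
  m2 <- simulate_haplotype_mosaic(20, 150, seed = 4)
  expect_identical(m1$genotypes, m2$genotypes)
})

test_that("no-selection config leaves the truth table empty", {
  cfg <- sim_config(n_populations = 4, n_variants = 200,
                    fraction_selected = 0, reference_pops = FALSE,
                    seed = 3)
  sim <- simulate_balding_nichols(cfg)
  expect_equal(nrow(sim$truth$selected), 0L)
})

test_that("planting selection shifts only the chosen loci", {
  cfg <- sim_config(n_populations = 10, n_variants = 500,
                    fraction_selected = 0, reference_pops = FALSE,
                    seed = 14)
  sim <- simulate_balding_nichols(cfg)
  loci <- sim$panel$variants$vid[c(10, 20, 30)]
  out <- plant_altitude_selection(sim$panel, sim$truth, sim$populations,
                                  loci, slope = 0.15, seed = 55)
  untouched <- setdiff(sim$panel$variants$vid, loci)
  ui <- match(untouched, sim$panel$variants$vid)
  expect_identical(out$panel$genotypes[, ui], sim$panel$genotypes[, ui])
  expect_setequal(out$truth$selected$vid, loci)

  # slope 0 leaves frequencies unchanged by construction
  out0 <- plant_altitude_selection(sim$panel, sim$truth, sim$populations,
                                   loci, slope = 0, seed = 55)
  li <- match(loci, colnames(sim$truth$pop_freq))
  expect_equal(out0$truth$pop_freq[, li],
               pmin(pmax(sim$truth$pop_freq[, li], 0.01), 0.99))

  # identical altitudes: planted frequencies all shift by the same amount
  flat_pops <- make_pops(rownames(sim$truth$pop_freq),
                         rep(1000, nrow(sim$truth$pop_freq)))
  outf <- plant_altitude_selection(sim$panel, sim$truth, flat_pops,
                                   loci, slope = 0.15, seed = 55)
  shift <- outf$truth$pop_freq[, li] - sim$truth$pop_freq[, li]
  inner <- abs(outf$truth$pop_freq[, li] - 0.5) < 0.48  # unclamped cells
  expect_true(all(abs(shift[inner] - 0.15) < 1e-12))
})

test_that("planted loci reach high frequency-altitude correlation", {
  cfg <- sim_config(n_populations = 20, n_samples = 20,
                    n_variants = 2000, fraction_selected = 0.01,
                    selection_slope = 0.15, selection_cluster_size = 1,
                    reference_pops = FALSE, seed = 101)
  sim <- simulate_balding_nichols(cfg)
  alt <- sim$populations$altitude_m[
    match(rownames(sim$truth$pop_freq), sim$populations$code)]
  sel <- match(sim$truth$selected$vid, colnames(sim$truth$pop_freq))
  rhos <- apply(sim$truth$pop_freq[, sel, drop = FALSE], 2,
                function(f) cor(f, alt, method = "spearman"))
  expect_gte(mean(rhos > 0.7), 0.9)
  # and a null slope gives rho centred on zero
  cfg0 <- sim_config(n_populations = 20, n_samples = 20,
                     n_variants = 500, fraction_selected = 0,
                     reference_pops = FALSE, seed = 102)
  sim0 <- simulate_balding_nichols(cfg0)
  rhos0 <- apply(sim0$truth$pop_freq[, 1:200], 2,
                 function(f) cor(f, sim0$populations$altitude_m[
                   match(rownames(sim0$truth$pop_freq),
                         sim0$populations$code)], method = "spearman"))
  expect_lt(abs(mean(rhos0)), 0.1)
})

test_that("admixture simulator mixes frequencies linearly", {
  withr::local_seed(8)
  fa <- runif(4000, 0.05, 0.95)
  fb <- pmin(pmax(fa + rnorm(4000, 0, 0.25), 0.01), 0.99)
  pure <- simulate_admixed_population(fa, fb, 1, 50, seed = 1)
  expect_equal(pure$freq, fa)

  mix <- simulate_admixed_population(fa, fb, 0.25, 400, seed = 2)
  obs <- colMeans(mix$genotypes) / 2
  # recover lambda by least squares on frequencies
  lam <- stats::coef(stats::lm(I(obs - fb) ~ 0 + I(fa - fb)))[[1]]
  expect_equal(lam, 0.25, tolerance = 0.05)
})

test_that("haplotype mosaic yields distance-decaying LD", {
  panel <- simulate_haplotype_mosaic(200, 400, n_founders = 8,
                                     n_chromosomes = 1, seed = 33)
  # no recombination: each haplotype is a founder
  frozen <- simulate_haplotype_mosaic(30, 100, n_founders = 2,
                                      n_chromosomes = 1, switch_scale = 0,
                                      seed = 34)
  founders <- attr(frozen, "founders")
  # with 2 founders and no switching, dosages are sums of 2 of at most 2
  # distinct haplotypes
  segregating <- founders[1, ] != founders[2, ]
  if (any(segregating)) {
    cols <- which(segregating)
    hap_id <- apply(frozen$genotypes[, cols, drop = FALSE], 1,
                    paste, collapse = "")
    expect_lte(length(unique(hap_id)), 3)  # f1f1, f1f2, f2f2
    # fully correlated segregating sites: r2 = 1
    if (length(cols) >= 2) {
      expect_equal(genotype_r2(frozen$genotypes[, cols[1]],
                               frozen$genotypes[, cols[2]]), 1)
    }
  }
  # mean r2 non-increasing across distance bins (Spearman over bins < 0)
  cm <- panel$variants$cm
  g <- panel$genotypes
  pairs <- t(utils::combn(seq_len(200), 2))  # first 200 variants
  d <- (cm[pairs[, 2]] - cm[pairs[, 1]])
  r2 <- vapply(seq_len(nrow(pairs)), function(k)
    genotype_r2(g[, pairs[k, 1]], g[, pairs[k, 2]]), 0)
  bins <- cut(d, breaks = quantile(d, seq(0, 1, 0.1)),
              include.lowest = TRUE)
  mr2 <- tapply(r2, bins, mean, na.rm = TRUE)
  expect_lt(cor(seq_along(mr2), mr2, method = "spearman"), 0)
})

test_that("planted ROH segments are homozygous and guarded", {
  panel <- simulate_haplotype_mosaic(10, 300, n_founders = 30,
                                     n_chromosomes = 1, seed = 41)
  with_roh <- plant_roh(panel, "SIM_001", "1", 50, 150, seed = 42)
  cols <- 50:199
  seg <- with_roh$genotypes[1, cols]
  expect_false(any(seg == 1L, na.rm = TRUE))
  # outside untouched
  expect_identical(with_roh$genotypes[1, -cols], panel$genotypes[1, -cols])
  expect_identical(with_roh$genotypes[-1, ], panel$genotypes[-1, ])
  # overlap guard and the zero-length no-op
  expect_error(plant_roh(with_roh, "SIM_001", "1", 100, 20, seed = 1),
               "overlap")
  same <- plant_roh(panel, "SIM_001", "1", 50, 0)
  expect_identical(same$genotypes, panel$genotypes)
})

test_that("LD-decay bin generator matches its closed form", {
  bins <- simulate_ld_decay_bins(1000, alpha = 1,
                                 c_bins = c(0.005, 0.05, 0.5))
  expect_equal(bins$r2_adj[1], 1 / 21)
  expect_lt(bins$r2_adj[3], 0.001)
  # doubling Ne halves r2 where 4 Ne c >> alpha
  b2 <- simulate_ld_decay_bins(2000, alpha = 1, c_bins = 0.5)
  expect_equal(bins$r2_adj[3] / b2$r2_adj[1], 2, tolerance = 0.05)
})
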