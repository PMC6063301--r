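het_rich_panel <- function(n_samples = 4, n_variants = 400, seed = 91) {
  # high-heterozygosity background so no spurious ROH is callable
  withr::with_seed(seed, {
    g <- matrix(rbinom(n_samples * n_variants, 2L, 0.5),
                nrow = n_samples)
    make_panel(g, pos = seq(5000L, by = 5000L, length.out = n_variants))
  })
}

test_that("ROH scan recovers a planted 150-SNP segment, rejects 99 SNPs", {
  p <- het_rich_panel()
  p150 <- plant_roh(p, "s1", "1", 101, 150, seed = 1)
  segs <- roh_scan(p150)
  mine <- segs[segs$sample_id == "s1", ]
  expect_equal(nrow(mine), 1L)
  expect_gte(mine$n_snps, 100)
  # boundaries within one window of the planted interval
  expect_lt(abs(mine$start_pos - p$variants$pos[101]), 50 * 5000)
  expect_lt(abs(mine$end_pos - p$variants$pos[250]), 50 * 5000)
  expect_equal(nrow(segs[segs$sample_id != "s1", ]), 0L)

  # 99-SNP segment is below the minimum and must not be called
  p99 <- plant_roh(p, "s2", "1", 101, 99, seed = 2)
  expect_equal(nrow(roh_scan(p99)[roh_scan(p99)$sample_id == "s2", ]), 0L)
})

test_that("a single heterozygote splits a run (het allowance zero)", {
  p <- het_rich_panel()
  p150 <- plant_roh(p, "s1", "1", 101, 150, seed = 3)
  mid <- 175L                       # inside the planted run
  p150$genotypes[1, mid] <- 1L
  segs <- roh_scan(p150)
  mine <- segs[segs$sample_id == "s1", ]
  # split halves are ~74 and ~75 SNPs: both below 100, nothing reported
  expect_equal(nrow(mine), 0L)

  # with a 220-SNP run, one het leaves one >=100 half
  p220 <- plant_roh(p, "s3", "1", 61, 220, seed = 4)
  p220$genotypes[3, 100] <- 1L      # split at SNP 40 of the run
  segs2 <- roh_scan(p220)
  mine2 <- segs2[segs2$sample_id == "s3", ]
  expect_equal(nrow(mine2), 1L)
  expect_true(all(mine2$n_het == 0))
})

test_that("reported segments satisfy their invariants on re-inspection", {
  p <- het_rich_panel(n_samples = 6, n_variants = 500, seed = 95)
  p <- plant_roh(p, "s1", "1", 51, 180, seed = 5)
  p <- plant_roh(p, "s4", "1", 301, 120, seed = 6)
  p$genotypes[2, sample(500, 12)] <- NA   # some missingness elsewhere
  segs <- roh_scan(p, miss_allow = 5)
  expect_gte(nrow(segs), 2L)
  for (k in seq_len(nrow(segs))) {
    si <- match(segs$sample_id[k], p$samples$sample_id)
    idx <- which(p$variants$chrom == segs$chrom[k] &
                   p$variants$pos >= segs$start_pos[k] &
                   p$variants$pos <= segs$end_pos[k])
    g <- p$genotypes[si, idx]
    expect_gte(length(idx), 100)
    expect_equal(sum(g == 1L, na.rm = TRUE), 0L)
    expect_lte(sum(is.na(g)), 5)
  }
})

test_that("lowering min_snps never removes a reported segment", {
  p <- het_rich_panel(n_samples = 3, n_variants = 450, seed = 97)
  p <- plant_roh(p, "s1", "1", 31, 130, seed = 7)
  p <- plant_roh(p, "s2", "1", 201, 105, seed = 8)
  strict <- roh_scan(p, min_snps = 120)
  loose <- roh_scan(p, min_snps = 100)
  key <- function(s) paste(s$sample_id, s$chrom, s$start_pos, s$end_pos)
  expect_true(all(key(strict) %in% key(loose)))
  expect_gte(nrow(loose), nrow(strict))
})

test_that("inbreeding F: HWE ~ 0, full homozygosity = 1, tracks ROH load", {
  withr::local_seed(14)
  m <- 20000
  g <- hwe_genotypes(10, m, runif(m, 0.1, 0.9))
  p <- make_panel(g)
  f <- inbreeding_f(p)
  expect_lt(max(abs(f$f)), 0.02)

  # fully homozygous sample
  g2 <- g
  g2[1, g2[1, ] == 1L] <- 0L
  f2 <- inbreeding_f(make_panel(g2))
  expect_equal(f2$f[1], 1, tolerance = 1e-12)

  # total planted ROH length correlates with F across samples
  p3 <- het_rich_panel(n_samples = 12, n_variants = 2000, seed = 99)
  lens <- round(seq(0, 1400, length.out = 12))
  for (i in seq_len(12)) {
    if (lens[i] > 0) {
      p3 <- plant_roh(p3, paste0("s", i), "1", 100, lens[i], seed = i)
    }
  }
  f3 <- inbreeding_f(p3)
  expect_gt(cor(lens, f3$f, method = "spearman"), 0.8)
})

test_that("Ne recovery from noiseless decay bins is exact to 1%", {
  bins <- simulate_ld_decay_bins(1000, alpha = 1,
                                 c_bins = seq(0.001, 0.05,
                                              length.out = 25))
  fit <- fit_ld_decay(bins$c, bins$r2_adj)
  expect_equal(fit$ne_long_term, 1000, tolerance = 0.01)
  expect_equal(fit$alpha, 1, tolerance = 0.01)
  expect_lt(fit$rss, 1e-12)
  # per-bin trajectory recovers the constant size
  expect_equal(mean(fit$bins$ne_t), 1000, tolerance = 0.01)
  expect_equal(fit$ne_harmonic, 1000, tolerance = 0.01)

  # t = 1/(2c): c = 0.05 Morgans -> 10 generations -> 290 years
  b <- fit$bins[abs(fit$bins$c - 0.05) < 1e-9, ]
  expect_equal(b$t_generations, 10)
  expect_equal(b$t_years, 290)
})

test_that("fitted Ne orders mosaic panels by founder-pool size", {
  # the decay slope carries only ~2*c_max relative signal, so the panels
  # need a long map span for the ordering to rise above founder noise
  breaks <- seq(0.0005, 0.05, length.out = 25)
  small <- simulate_haplotype_mosaic(100, 2000, n_founders = 8,
                                     n_chromosomes = 1, seed = 111)
  large <- simulate_haplotype_mosaic(100, 2000, n_founders = 120,
                                     n_chromosomes = 1, seed = 112)
  ne_small <- ne_from_ld(small, "SIM", c_breaks = breaks)
  ne_large <- ne_from_ld(large, "SIM", c_breaks = breaks)
  expect_lt(ne_small$ne_long_term, ne_large$ne_long_term)
  expect_error(ne_from_ld(small, "SIM", min_n = 200), "samples")
})

test_that("faster map decay steepens the fitted slope", {
  breaks <- seq(0.0005, 0.05, length.out = 25)
  slow <- simulate_haplotype_mosaic(100, 2000, n_founders = 16,
                                    n_chromosomes = 1, switch_scale = 1,
                                    seed = 113)
  fast <- simulate_haplotype_mosaic(100, 2000, n_founders = 16,
                                    n_chromosomes = 1, switch_scale = 10,
                                    seed = 113)
  b_slow <- ne_from_ld(slow, "SIM", c_breaks = breaks)$beta
  b_fast <- ne_from_ld(fast, "SIM", c_breaks = breaks)$beta
  expect_gt(b_fast, b_slow)
})

test_that("divergence time closed form, monotonicity and recovery", {
  expect_equal(divergence_time(0, 1000)$t_generations, 0)
  dt <- divergence_time(0.05, 1000)
  expect_equal(dt$t_generations, -2000 * log(0.95), tolerance = 1e-12)
  expect_equal(dt$t_generations, 102.59, tolerance = 1e-4)
  expect_equal(dt$t_years, dt$t_generations * 29)
  expect_error(divergence_time(1, 1000), "fst")

  # monotone in both arguments
  expect_gt(divergence_time(0.1, 1000)$t_generations,
            divergence_time(0.05, 1000)$t_generations)
  expect_gt(divergence_time(0.05, 2000)$t_generations,
            divergence_time(0.05, 1000)$t_generations)

  # generative recovery: Balding-Nichols drift F ~ T/(2Ne) per population;
  # two populations split T generations ago, Ne = 500, T = 80
  ne_true <- 500; t_true <- 80
  f_drift <- t_true / (2 * ne_true)
  cfg <- sim_config(n_populations = 2, n_samples = 40,
                    f_pop = rep(f_drift, 2), altitude_m = c(100, 3000),
                    n_variants = 8000, fraction_selected = 0,
                    freq_range = c(0.2, 0.8),
                    reference_pops = FALSE, seed = 115)
  sim <- simulate_balding_nichols(cfg)
  fst_mean <- mean(pairwise_fst(sim$panel, "P01", "P02")$fst, na.rm = TRUE)
  t_hat <- divergence_time(fst_mean, ne_true)$t_generations
  expect_equal(t_hat, t_true, tolerance = 0.25)
})
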