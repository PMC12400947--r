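# Synthetic low-pass imputation cohort generator

test_that("truth simulation is deterministic and recovers HWE proportions", {
  cfg <- sim_config(n_samples = 50, n_variants = 100, seed = 99)
  a <- simulate_truth(cfg)
  b <- simulate_truth(cfg)
  expect_identical(a$truth$dosage, b$truth$dosage)
  expect_identical(a$af$af, b$af$af)

  # at AF 0.5 and n = 1e4, the het fraction sits within 3 SE of 1/2
  cfg2 <- sim_config(n_samples = 10000, n_variants = 3,
                     af_model = af_fixed(0.5), seed = 5)
  tr <- simulate_truth(cfg2)$truth
  se <- sqrt(0.5 * 0.5 / 10000)
  for (i in 1:3) {
    expect_lt(abs(mean(tr$dosage[i, ] == 1L) - 0.5), 3 * se)
  }
  # full genotype-frequency recovery at an asymmetric frequency
  cfg3 <- sim_config(n_samples = 10000, n_variants = 2,
                     af_model = af_fixed(0.2), seed = 6)
  tr3 <- simulate_truth(cfg3)$truth
  for (i in 1:2) {
    p <- tabulate(tr3$dosage[i, ] + 1L, 3) / 10000
    exp_p <- c(0.64, 0.32, 0.04)
    se_p <- sqrt(exp_p * (1 - exp_p) / 10000)
    expect_true(all(abs(p - exp_p) < 3 * se_p + 1e-12))
  }
})

test_that("AF 0 gives all hom-ref; fully degenerate AF models are rejected", {
  cfg <- sim_config(n_samples = 30, n_variants = 4,
                    af_model = af_fixed(c(0, 0.5)), seed = 3)
  tr <- simulate_truth(cfg)$truth
  expect_true(all(tr$dosage[c(1, 3), ] == 0L))
  expect_error(af_fixed(c(0, 0)), "degenerate")
})

test_that("zero coverage yields zero reads and INFO exactly 0", {
  cfg <- sim_config(n_samples = 25, n_variants = 10, coverage = 0, seed = 2)
  sim <- simulate_truth(cfg)
  reads <- simulate_reads(sim$truth, sim$af, cfg)
  expect_true(all(reads$n == 0))
  imp <- posterior_gp(reads, sim$af, cfg$base_error)
  # depth 0: the posterior equals the HWE prior...
  af1 <- sim$af$af[1]
  expect_equal(imp$gp_het[1, 1], 2 * af1 * (1 - af1), tolerance = 1e-12)
  # ...so every variant's INFO score is exactly zero
  expect_identical(unname(batch_info_scores(imp)), rep(0, 10))
})

test_that("pooled alt-read fractions match the mixture model", {
  # maternal hom-alt, no fetal mixture: alt fraction = 1 - base_error
  cfg <- sim_config(n_samples = 400, n_variants = 30, coverage = 2,
                    imputation_gain = 1, coverage_rel_sd = 0,
                    af_model = af_fixed(1), base_error = 0.01, seed = 8)
  sim <- simulate_truth(cfg)
  expect_true(all(sim$truth$dosage == 2L))
  reads <- simulate_reads(sim$truth, sim$af, cfg)
  n_tot <- sum(reads$n)
  frac <- sum(reads$n_alt) / n_tot
  se <- sqrt(0.01 * 0.99 / n_tot)
  expect_lt(abs(frac - 0.99), 3 * se)

  # maternal hom-ref at AF -> 0 with ff = 0.5: fetal allele almost surely
  # ref, so the alt fraction stays at the error floor
  cfg2 <- sim_config(n_samples = 400, n_variants = 30, coverage = 2,
                     imputation_gain = 1, coverage_rel_sd = 0,
                     af_model = af_fixed(1e-6), fetal_fraction = 0.5,
                     base_error = 0.01, seed = 9)
  sim2 <- simulate_truth(cfg2)
  reads2 <- simulate_reads(sim2$truth, sim2$af, cfg2)
  hom_ref_cells <- sim2$truth$dosage == 0L
  n_tot2 <- sum(reads2$n[hom_ref_cells])
  frac2 <- sum(reads2$n_alt[hom_ref_cells]) / n_tot2
  se2 <- sqrt(0.01 * 0.99 / n_tot2)
  expect_lt(abs(frac2 - 0.01), 4 * se2)

  # maternal het with ff = 0.5: half the fetal genotypes carry the
  # untransmitted population allele, shifting the expected alt fraction
  # towards 0.5 * 0.5 + 0.5 * E[mu(g_f)] — checked against the formula
  cfg3 <- sim_config(n_samples = 400, n_variants = 30, coverage = 2,
                     imputation_gain = 1, coverage_rel_sd = 0,
                     af_model = af_fixed(0.5), fetal_fraction = 0.4,
                     base_error = 0.01, seed = 10)
  sim3 <- simulate_truth(cfg3)
  reads3 <- simulate_reads(sim3$truth, sim3$af, cfg3)
  het_cells <- sim3$truth$dosage == 1L
  # E[mu(g_f) | maternal het, AF 0.5]: transmitted allele Bern(0.5),
  # population allele Bern(0.5) -> g_f ~ (1/4, 1/2, 1/4)
  e_mu_f <- 0.25 * 0.01 + 0.5 * 0.5 + 0.25 * 0.99
  expected <- 0.6 * 0.5 + 0.4 * e_mu_f
  n_tot3 <- sum(reads3$n[het_cells])
  frac3 <- sum(reads3$n_alt[het_cells]) / n_tot3
  expect_lt(abs(frac3 - expected), 4 * sqrt(0.25 / n_tot3) + 0.01)
})

test_that("posteriors agree with a direct Bayes computation", {
  variants <- tibble::tibble(chrom = "1", pos = 100L, ref = "A", alt = "G",
                             key = "1:100:A:G")
  af <- tibble::tibble(chrom = "1", pos = 100L, ref = "A", alt = "G",
                       af = 0.5, key = "1:100:A:G")
  mk_reads <- function(n, n_alt) {
    structure(list(n = matrix(n, 1, 1), n_alt = matrix(n_alt, 1, 1),
                   variants = variants, samples = "S01", sample_factor = 1),
              class = "read_counts")
  }
  bayes <- function(n, n_alt, af, eps) {
    prior <- c((1 - af)^2, 2 * af * (1 - af), af^2)
    lik <- c(dbinom(n_alt, n, eps), dbinom(n_alt, n, 0.5),
             dbinom(n_alt, n, 1 - eps))
    w <- prior * lik
    w / sum(w)
  }
  # 50 reference reads: overwhelming hom-ref evidence
  imp <- posterior_gp(mk_reads(50, 0), af, base_error = 0.01)
  want <- bayes(50, 0, 0.5, 0.01)
  expect_equal(imp$gp_homref[1, 1], want[1], tolerance = 1e-12)
  expect_equal(imp$gt[1, 1], 0L)
  expect_gt(imp$gp_homref[1, 1], 0.99)
  # a single alt read
  imp2 <- posterior_gp(mk_reads(1, 1), af, base_error = 0.01)
  want2 <- bayes(1, 1, 0.5, 0.01)
  expect_equal(c(imp2$gp_homref[1, 1], imp2$gp_het[1, 1],
                 imp2$gp_homalt[1, 1]), want2, tolerance = 1e-12)
  expect_equal(imp2$ds[1, 1], want2[2] + 2 * want2[3], tolerance = 1e-12)
})

test_that("batched simulation partitions samples and is reproducible", {
  cfg <- sim_config(n_samples = 30, n_variants = 40, n_batches = 3, seed = 21)
  sim <- simulate_batches(cfg)
  expect_length(sim$batches, 3L)
  expect_equal(vapply(sim$batches, n_samples, 1L), rep(10L, 3))
  expect_equal(unique(vapply(sim$batches, n_variants, 1L)), 40L)
  # per-batch quality carries that batch's recomputed INFO
  b1 <- sim$batches[[1]]
  expect_equal(b1$variant_quality, unname(batch_info_scores(b1)),
               tolerance = 1e-12)
  sim2 <- simulate_batches(cfg)
  expect_identical(sim$batches[[2]]$gp_het, sim2$batches[[2]]$gp_het)
  expect_identical(sim$truth$dosage, sim2$truth$dosage)
  expect_error(sim_config(n_samples = 2, n_batches = 3), "n_batches")
})

test_that("higher coverage concentrates posteriors", {
  hi <- sim_config(n_samples = 40, n_variants = 300, coverage = 1.0,
                   n_batches = 1, seed = 31)
  lo <- sim_config(n_samples = 40, n_variants = 300, coverage = 0.1,
                   n_batches = 1, seed = 31)
  m_hi <- simulate_batches(hi)$batches[[1]]
  m_lo <- simulate_batches(lo)$batches[[1]]
  gpm_hi <- mean(pmax(m_hi$gp_homref, m_hi$gp_het, m_hi$gp_homalt))
  gpm_lo <- mean(pmax(m_lo$gp_homref, m_lo$gp_het, m_lo$gp_homalt))
  expect_gt(gpm_hi, gpm_lo)
})
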