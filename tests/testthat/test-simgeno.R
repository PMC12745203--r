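test_that("variant sampling honours config and is deterministic", {
  cfg <- sim_config(n_subjects = 10, m_snps = 10, k_causal = 0, seed = 1)
  v <- sample_variants(cfg)
  expect_equal(nrow(v), 10)
  expect_true(all(v$beta_true == 0))
  expect_false(any(v$is_causal))

  cfg2 <- sim_config(n_subjects = 10, m_snps = 100, k_causal = 10, seed = 1)
  expect_identical(sample_variants(cfg2), sample_variants(cfg2))
  v2 <- sample_variants(cfg2)
  expect_equal(sum(v2$is_causal), 10)
  expect_true(all(abs(v2$beta_true[v2$is_causal]) >= log(2) - 1e-12))
  expect_false(is.unsorted(v2$pos, strictly = TRUE))
  expect_false(anyDuplicated(v2$snp_id) > 0)

  cfg3 <- sim_config(n_subjects = 10, m_snps = 20, k_causal = 0,
                     maf_range = c(0.3, 0.3), seed = 2)
  expect_true(all(sample_variants(cfg3)$ancestral_maf == 0.3))

  expect_error(sim_config(n_subjects = 10, m_snps = 5, k_causal = 6, seed = 1),
               "k_causal")
  expect_error(sim_config(n_subjects = 10, m_snps = 5, seed = 1,
                          maf_range = c(0.4, 0.2)), "maf_range")
  expect_error(sim_config(n_subjects = 10, m_snps = 5, k_causal = 0,
                          fst = 1, seed = 1), "fst")
  expect_error(sim_config(n_subjects = 10, m_snps = 5, k_causal = 0),
               "seed")
})

test_that("genotypes follow Hardy-Weinberg proportions within subpopulations", {
  cfg <- sim_config(n_subjects = 10000, m_snps = 1, k_causal = 0,
                    maf_range = c(0.5, 0.5), n_subpops = 1, fst = 0,
                    missing_rate = 0, seed = 5)
  v <- sample_variants(cfg)
  G <- simulate_genotypes(v, assign_subpops(cfg), cfg)
  freq <- tabulate(G[, 1] + 1L, 3L) / nrow(G)
  hwe <- c(0.25, 0.5, 0.25)
  se <- sqrt(hwe * (1 - hwe) / nrow(G))
  expect_true(all(abs(freq - hwe) < 3 * se))
})

test_that("genotype alphabet and determinism hold, including under structure", {
  cfg <- sim_config(n_subjects = 100, m_snps = 10, k_causal = 0,
                    maf_range = c(0.01, 0.01), n_subpops = 1, fst = 0,
                    missing_rate = 0, seed = 6)
  v <- sample_variants(cfg)
  G <- simulate_genotypes(v, assign_subpops(cfg), cfg)
  expect_true(all(G %in% 0:2))

  cfg2 <- sim_config(n_subjects = 60, m_snps = 15, k_causal = 0,
                     n_subpops = 2, fst = 0.2, missing_rate = 0, seed = 9)
  v2 <- sample_variants(cfg2)
  sp <- assign_subpops(cfg2)
  expect_identical(simulate_genotypes(v2, sp, cfg2),
                   simulate_genotypes(v2, sp, cfg2))
})

test_that("empirical allele frequencies converge to subpop frequencies", {
  cfg <- sim_config(n_subjects = 6000, m_snps = 30, k_causal = 0,
                    n_subpops = 1, fst = 0, missing_rate = 0, seed = 8)
  v <- sample_variants(cfg)
  G <- simulate_genotypes(v, assign_subpops(cfg), cfg)
  p_hat <- colMeans(G) / 2
  p <- attr(G, "subpop_freq")[, 1]
  expect_true(all(abs(p_hat - p) < 3 * sqrt(p * (1 - p) / (2 * nrow(G)))))
})

test_that("mean Wright's Fst across SNPs recovers the configured divergence", {
  F <- 0.1
  cfg <- sim_config(n_subjects = 2000, m_snps = 600, k_causal = 0,
                    maf_range = c(0.2, 0.5), n_subpops = 2, fst = F,
                    missing_rate = 0, seed = 10)
  v <- sample_variants(cfg)
  sp <- assign_subpops(cfg)
  G <- simulate_genotypes(v, sp, cfg)
  p1 <- colMeans(G[sp == 1, ]) / 2
  p2 <- colMeans(G[sp == 2, ]) / 2
  # E[(p1-p2)^2] = 2 F p0 (1-p0) under Balding-Nichols
  fst_hat <- mean((p1 - p2)^2 / (2 * v$ancestral_maf * (1 - v$ancestral_maf)))
  expect_lt(abs(fst_hat - F) / F, 0.3)
})

test_that("simulated genotype counts pass the HWE test at nominal rates", {
  cfg <- sim_config(n_subjects = 1000, m_snps = 400, k_causal = 0,
                    maf_range = c(0.1, 0.5), n_subpops = 1, fst = 0,
                    missing_rate = 0, seed = 11)
  v <- sample_variants(cfg)
  G <- simulate_genotypes(v, assign_subpops(cfg), cfg)
  pvals <- apply(G, 2, function(g)
    hwe_test(sum(g == 0), sum(g == 1), sum(g == 2))$p)
  expect_lte(mean(pvals < 0.05), 0.07)
})

test_that("phenotype intercept calibration matches the closed-form logit", {
  cfg <- sim_config(n_subjects = 10000, m_snps = 5, k_causal = 0,
                    covariate_effects = c(gamma_age = 0, gamma_sex = 0),
                    case_fraction_target = 0.176, n_subpops = 1, fst = 0,
                    missing_rate = 0, seed = 12)
  v <- sample_variants(cfg)
  G <- simulate_genotypes(v, assign_subpops(cfg), cfg)
  ph <- simulate_phenotypes(G, v, cfg)
  expect_equal(attr(ph, "beta0"), qlogis(0.176), tolerance = 1e-3)
  expect_true(all(ph$age >= 18))

  cfg5 <- sim_config(n_subjects = 10000, m_snps = 5, k_causal = 0,
                     covariate_effects = c(gamma_age = 0, gamma_sex = 0),
                     case_fraction_target = 0.5, n_subpops = 1, fst = 0,
                     missing_rate = 0, seed = 13)
  ph5 <- simulate_phenotypes(G, v, cfg5)
  expect_lt(abs(attr(ph5, "beta0")), 1e-3)
  expect_lt(abs(mean(ph5$status) - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("case rate increases monotonically over genotype groups of a causal SNP", {
  cfg <- sim_config(n_subjects = 10000, m_snps = 1, k_causal = 0,
                    maf_range = c(0.4, 0.4),
                    covariate_effects = c(gamma_age = 0, gamma_sex = 0),
                    case_fraction_target = 0.3, n_subpops = 1, fst = 0,
                    missing_rate = 0, seed = 14)
  v <- sample_variants(cfg)
  v$beta_true <- log(3); v$is_causal <- TRUE
  G <- simulate_genotypes(v, assign_subpops(cfg), cfg)
  ph <- simulate_phenotypes(G, v, cfg)
  rates <- tapply(ph$status, G[, 1], mean)
  expect_true(all(diff(rates) > 0))
})

test_that("missingness injection is binomial, seed-stable and optional", {
  cfg <- sim_config(n_subjects = 100, m_snps = 100, k_causal = 0,
                    missing_rate = 0, n_subpops = 1, fst = 0, seed = 15)
  v <- sample_variants(cfg)
  G <- simulate_genotypes(v, assign_subpops(cfg), cfg)
  expect_identical(inject_missingness(G, 0, seed = 1), G)
  M <- inject_missingness(G, 0.5, seed = 2)
  expect_lt(abs(sum(is.na(M)) - 5000), 3 * sqrt(10000 * 0.25))
  expect_identical(inject_missingness(G, 0.05, seed = 3),
                   inject_missingness(G, 0.05, seed = 3))
  expect_error(inject_missingness(G, 1.2, seed = 1), "rate")
})

test_that("full dataset simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_subjects = 150, m_snps = 40, k_causal = 5,
                    missing_rate = 0.03, seed = 16)
  b1 <- simulate_dataset(cfg)
  b2 <- simulate_dataset(cfg)
  expect_identical(b1, b2)
  expect_lt(abs(mean(is.na(b1$genotypes)) - 0.03), 0.01)
})
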