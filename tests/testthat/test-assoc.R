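# Direct maximum-likelihood oracle for the per-SNP logistic fit:
# quasi-Newton maximization with the analytic gradient, standard errors
# from the analytic observed information at the optimum.
ml_oracle <- function(g, y, covs) {
  X <- cbind(1, g, covs)
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(y * eta - log1p(exp(eta)))
  }
  gr <- function(beta) -drop(crossprod(X, y - plogis(drop(X %*% beta))))
  o <- stats::optim(rep(0, ncol(X)), nll, gr = gr, method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-16))
  p <- plogis(drop(X %*% o$par))
  H <- crossprod(X, X * (p * (1 - p)))
  list(beta = o$par[2], se = sqrt(diag(solve(H)))[2])
}

sim_small_instance <- function(seed) {
  set.seed(seed)
  n <- 60
  g <- rbinom(n, 2, runif(1, 0.2, 0.45))
  age <- rnorm(n)
  sex <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.3 + runif(1, -0.8, 0.8) * g + 0.3 * age))
  if (var(g) == 0 || length(unique(y)) < 2) return(NULL)
  list(g = g, y = y, covs = cbind(age = age, sex = sex),
       pheno = data.frame(sample_id = sprintf("S%02d", 1:n), status = y,
                          age = age, sex = sex, stringsAsFactors = FALSE))
}

test_that("IRLS estimates equal direct likelihood maximization to 1e-6", {
  n_checked <- 0
  for (seed in 1:30) {
    inst <- sim_small_instance(seed)
    if (is.null(inst)) next
    G <- matrix(inst$g, dimnames = list(inst$pheno$sample_id, "s1"))
    sc <- logistic_scan(G, inst$pheno, inst$covs)
    if (!sc$converged || sc$separation_flag) next
    or <- ml_oracle(inst$g, inst$y, inst$covs)
    expect_lt(abs(sc$beta - or$beta), 1e-6)
    expect_lt(abs(sc$se - or$se), 1e-6)
    n_checked <- n_checked + 1
    if (n_checked >= 20) break
  }
  expect_gte(n_checked, 20)
})

test_that("null p-values are uniform and the Wald test holds its size", {
  cfg <- sim_config(n_subjects = 2000, m_snps = 1000, k_causal = 0,
                    maf_range = c(0.1, 0.5), n_subpops = 1, fst = 0,
                    case_fraction_target = 0.3, missing_rate = 0, seed = 21)
  b <- simulate_dataset(cfg)
  covs <- covariate_table(b$phenotypes)
  sc <- logistic_scan(b$genotypes * 1.0, b$phenotypes, covs,
                      variants = b$variants)
  p <- sc$p[!is.nan(sc$p)]
  expect_gte(length(p), 990)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
  rej <- mean(p < 0.05)
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("effect sizes are recovered for a causal SNP", {
  set.seed(77)
  betas <- replicate(100, {
    n <- 2000
    g <- rbinom(n, 2, 0.3)
    y <- rbinom(n, 1, plogis(-1 + log(3) * g))
    covs <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
    ph <- data.frame(sample_id = sprintf("S%04d", 1:n), status = y,
                     age = covs[, 1], sex = covs[, 2],
                     stringsAsFactors = FALSE)
    logistic_scan(matrix(g, dimnames = list(ph$sample_id, "s")), ph, covs)$beta
  })
  expect_lt(abs(median(betas) - log(3)) / log(3), 0.15)
})

test_that("monomorphic SNPs are flagged and excluded from subsets", {
  n <- 100
  set.seed(5)
  G <- cbind(mono = rep(1, n), ok = rbinom(n, 2, 0.4))
  rownames(G) <- sprintf("S%03d", 1:n)
  ph <- data.frame(sample_id = rownames(G),
                   status = rbinom(n, 1, 0.4), age = rnorm(n),
                   sex = rbinom(n, 1, 0.5), stringsAsFactors = FALSE)
  sc <- logistic_scan(G, ph, covariate_table(ph))
  expect_true(is.nan(sc$p[1]))
  expect_false(sc$converged[1])
  subs <- suppressWarnings(select_snp_subsets(sc, thresholds = 0.99))
  expect_false("mono" %in% subs[[1]])
})

test_that("PC1 separates strongly diverged subpopulations", {
  cfg <- sim_config(n_subjects = 1000, m_snps = 500, k_causal = 0,
                    maf_range = c(0.1, 0.5), n_subpops = 2, fst = 0.15,
                    missing_rate = 0, seed = 23)
  v <- sample_variants(cfg)
  sp <- assign_subpops(cfg)
  G <- simulate_genotypes(v, sp, cfg)
  pcs <- compute_pcs(G * 1.0, k = 2)
  expect_gt(abs(cor(pcs[, 1], sp)), 0.9)
  expect_lt(abs(mean(pcs[, 1])), 1e-8)
})

test_that("panmictic data shows no dominant principal component", {
  # n >> m so the Marchenko-Pastur bulk edge (1 + sqrt(m/n))^2 sits well
  # below the asserted bound; a dominant structure axis would exceed it
  cfg <- sim_config(n_subjects = 1500, m_snps = 150, k_causal = 0,
                    maf_range = c(0.1, 0.5), n_subpops = 1, fst = 0,
                    missing_rate = 0, seed = 24)
  v <- sample_variants(cfg)
  G <- simulate_genotypes(v, assign_subpops(cfg), cfg)
  pcs <- compute_pcs(G * 1.0, k = 2)
  ev <- attr(pcs, "eigenvalues")
  expect_lt(ev[1] / mean(ev), 3)
})

test_that("duplicated subjects receive identical PC scores", {
  cfg <- sim_config(n_subjects = 80, m_snps = 60, k_causal = 0,
                    missing_rate = 0, seed = 25)
  v <- sample_variants(cfg)
  G <- simulate_genotypes(v, assign_subpops(cfg), cfg)
  G2 <- rbind(G, G)
  rownames(G2) <- sprintf("D%03d", seq_len(nrow(G2)))
  pcs <- compute_pcs(G2 * 1.0, k = 2)
  expect_equal(pcs[1:80, ], pcs[81:160, ], ignore_attr = TRUE)
  expect_error(compute_pcs(G * 1.0, k = 1000), "rank")
})

test_that("PC adjustment restores calibration under population stratification", {
  cfg <- sim_config(n_subjects = 1000, m_snps = 500, k_causal = 0,
                    maf_range = c(0.1, 0.5), n_subpops = 2, fst = 0.15,
                    missing_rate = 0, seed = 26)
  v <- sample_variants(cfg)
  sp <- assign_subpops(cfg)
  G <- simulate_genotypes(v, sp, cfg) * 1.0
  set.seed(27)
  status <- rbinom(nrow(G), 1, plogis(-1 + 1.2 * (sp == 2)))
  ph <- data.frame(sample_id = rownames(G), status = status,
                   age = rnorm(nrow(G)), sex = rbinom(nrow(G), 1, 0.5),
                   stringsAsFactors = FALSE)
  sc_raw <- logistic_scan(G, ph, covariate_table(ph))
  pcs <- compute_pcs(G, k = 2)
  sc_adj <- logistic_scan(G, ph, covariate_table(ph, pcs))
  rej_raw <- mean(sc_raw$p < 0.05, na.rm = TRUE)
  rej_adj <- mean(sc_adj$p < 0.05, na.rm = TRUE)
  expect_gt(rej_raw, 0.07)
  expect_gte(rej_adj, 0.02)
  expect_lte(rej_adj, 0.08)
})

test_that("threshold subsets use strict inequality, skip NaN and nest", {
  sc <- data.frame(snp_id = c("a", "b", "c"), p = c(0.04, 0.004, 0.5))
  s1 <- select_snp_subsets(sc, thresholds = c(5e-2, 5e-3))
  expect_identical(s1[["5e-02"]], c("a", "b"))
  expect_identical(s1[["5e-03"]], "b")

  sc$p <- NaN
  expect_warning(s_all <- select_snp_subsets(sc, thresholds = c(5e-2)),
                 "empty")
  expect_length(s_all[[1]], 0)

  set.seed(1)
  scr <- data.frame(snp_id = sprintf("s%03d", 1:200), p = runif(200))
  subs <- suppressWarnings(select_snp_subsets(scr))
  for (i in seq_len(length(subs) - 1))
    expect_true(all(subs[[i + 1]] %in% subs[[i]]))
  # exactly at the threshold is excluded (strict <)
  sc2 <- data.frame(snp_id = "x", p = 5e-3)
  expect_length(suppressWarnings(
    select_snp_subsets(sc2, thresholds = 5e-3))[[1]], 0)
})
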