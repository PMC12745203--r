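#' Simulation configuration for synthetic case-control genotype data
#'
#' Bundles every parameter of the synthetic-data generator: cohort size and
#' case share, SNP panel size and allele-frequency range, planted causal
#' effects on the logistic scale, population structure (number of
#' subpopulations and their Fst divergence under the Balding-Nichols model),
#' age/sex covariate effects that confound case status, and the missing-call
#' rate. Defaults emulate a post-surgical sepsis case-control study design:
#' about 17.6% cases, two ancestry subpopulations, cases older and more often
#' male than controls.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param case_fraction_target Expected fraction of cases, in (0,1).
#' @param m_snps Number of biallelic SNPs in the panel.
#' @param maf_range Length-2 vector; ancestral minor-allele frequencies are
#'   drawn uniformly from this interval, each value in (0, 0.5].
#' @param k_causal Number of causal SNPs (`<= m_snps`).
#' @param causal_log_or_range Length-2 vector of per-alt-allele log odds
#'   ratio magnitudes; causal effects get a uniform magnitude from this range
#'   and a random sign.
#' @param n_subpops Number of subpopulations (`>= 1`).
#' @param fst Wright's Fst divergence of subpopulation allele frequencies
#'   from the ancestral frequency, in [0, 1). 0 means panmixia.
#' @param covariate_effects Named numeric vector `c(gamma_age=, gamma_sex=)`:
#'   per-year log odds ratio of (centered) age, and log odds ratio of sex
#'   (coded 0/1) on case status.
#' @param age_distribution Named numeric vector `c(mean=, sd=)` of the age
#'   distribution in years (normal, truncated below at 18).
#' @param missing_rate Probability that any genotype call is missing, [0,1).
#' @param seed Integer seed; mandatory, drives every random draw.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 4250L,
                       case_fraction_target = 0.176,
                       m_snps = 1000L,
                       maf_range = c(0.05, 0.5),
                       k_causal = 10L,
                       causal_log_or_range = c(log(2), log(3)),
                       n_subpops = 2L,
                       fst = 0.05,
                       covariate_effects = c(gamma_age = 0.08, gamma_sex = 0.45),
                       age_distribution = c(mean = 50, sd = 15),
                       missing_rate = 0.02,
                       seed = NULL) {
  if (is.null(seed)) stop_config("sim_config: `seed` is mandatory")
  if (!is_count(n_subjects)) stop_config("n_subjects must be a positive count")
  if (!is_count(m_snps)) stop_config("m_snps must be a positive count")
  if (!is_prop(case_fraction_target, 0, 1, TRUE, TRUE))
    stop_config("case_fraction_target must lie in (0,1)")
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop_config("maf_range must be (lo, hi) with 0 < lo <= hi <= 0.5")
  if (!(is_count(k_causal) || k_causal == 0) || k_causal > m_snps)
    stop_config("k_causal must be a count <= m_snps")
  if (length(causal_log_or_range) != 2L ||
      causal_log_or_range[1] > causal_log_or_range[2] ||
      any(causal_log_or_range < 0))
    stop_config("causal_log_or_range must be non-negative (lo, hi) magnitudes")
  if (!is_count(n_subpops)) stop_config("n_subpops must be a count >= 1")
  if (!is_prop(fst, 0, 1, FALSE, TRUE)) stop_config("fst must lie in [0,1)")
  if (!is_prop(missing_rate, 0, 1, FALSE, TRUE))
    stop_config("missing_rate must lie in [0,1)")
  if (age_distribution[["sd"]] < 0) stop_config("age sd must be >= 0")
  structure(list(
    n_subjects = as.integer(n_subjects),
    case_fraction_target = case_fraction_target,
    m_snps = as.integer(m_snps),
    maf_range = as.numeric(maf_range),
    k_causal = as.integer(k_causal),
    causal_log_or_range = as.numeric(causal_log_or_range),
    n_subpops = as.integer(n_subpops),
    fst = fst,
    covariate_effects = covariate_effects,
    age_distribution = age_distribution,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Draw the SNP panel (variant table) for a simulation
#'
#' Creates `m_snps` biallelic variants on a single synthetic chromosome with
#' strictly increasing positions, ancestral minor-allele frequencies drawn
#' uniformly from `maf_range`, and exactly `k_causal` variants flagged causal
#' with per-alt-allele log odds ratios of uniform magnitude (from
#' `causal_log_or_range`) and random sign. The alt allele is the minor allele
#' by construction (`ancestral_maf <= 0.5`).
#'
#' @param config A [sim_config()].
#' @return A `data.frame` (class `variant_table`) with columns `chrom`,
#'   `pos`, `snp_id`, `ref_allele`, `alt_allele`, `ancestral_maf`,
#'   `is_causal`, `beta_true`, `annotation`.
#' @export
sample_variants <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  m <- config$m_snps
  pos <- sort(sample.int(m * 1000L, m))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  beta <- numeric(m)
  causal <- logical(m)
  if (config$k_causal > 0) {
    idx <- sort(sample.int(m, config$k_causal))
    causal[idx] <- TRUE
    mag <- stats::runif(config$k_causal, config$causal_log_or_range[1],
                        config$causal_log_or_range[2])
    beta[idx] <- mag * sample(c(-1, 1), config$k_causal, replace = TRUE)
  }
  out <- data.frame(
    chrom = "1",
    pos = pos,
    snp_id = sprintf("snp%06d", seq_len(m)),
    ref_allele = ref,
    alt_allele = alt,
    ancestral_maf = maf,
    is_causal = causal,
    beta_true = beta,
    annotation = NA_character_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Assign subjects to subpopulations
#'
#' Balanced random assignment of `n` subjects to `n_subpops` groups.
#'
#' @param config A [sim_config()].
#' @return Integer vector of subpopulation labels in `1..n_subpops`.
#' @export
assign_subpops <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 2L))
  sample(rep_len(seq_len(config$n_subpops), config$n_subjects))
}

#' Simulate genotype calls under the Balding-Nichols model
#'
#' For each subpopulation `s` and SNP `j`, a subpopulation allele frequency
#' `p_sj` is drawn from `Beta(p_j (1-F)/F, (1-p_j)(1-F)/F)` when `F > 0`
#' (`p_sj = p_j` when `F = 0`), then genotypes are drawn as
#' `Binomial(2, p_sj)` independently per subject, i.e. Hardy-Weinberg
#' equilibrium within each subpopulation.
#'
#' @param variants A [sample_variants()] table.
#' @param subpops Integer subpopulation labels, one per subject
#'   (see [assign_subpops()]).
#' @param config A [sim_config()].
#' @return Integer matrix `n_subjects x m_snps` over {0,1,2} with
#'   `sample_ids` as rownames and `snp_id`s as colnames.
#' @export
simulate_genotypes <- function(variants, subpops, config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(subpops) != config$n_subjects)
    stop_config("subpops length must equal n_subjects")
  if (nrow(variants) != config$m_snps)
    stop_config("variants inconsistent with config (m_snps)")
  F <- config$fst
  set.seed(derive_seed(config$seed, 3L))
  n <- config$n_subjects
  m <- config$m_snps
  p0 <- variants$ancestral_maf
  n_sp <- config$n_subpops
  # subpop-specific allele frequencies, m x n_subpops
  if (F > 0) {
    a <- p0 * (1 - F) / F
    b <- (1 - p0) * (1 - F) / F
    psj <- matrix(stats::rbeta(m * n_sp, rep(a, n_sp), rep(b, n_sp)), m, n_sp)
  } else {
    psj <- matrix(rep(p0, n_sp), m, n_sp)
  }
  G <- matrix(0L, n, m)
  for (s in seq_len(n_sp)) {
    rows <- which(subpops == s)
    if (!length(rows)) next
    G[rows, ] <- matrix(
      stats::rbinom(length(rows) * m, 2L, rep(psj[, s], each = length(rows))),
      length(rows), m)
  }
  dimnames(G) <- list(sprintf("S%05d", seq_len(n)), variants$snp_id)
  attr(G, "subpop_freq") <- psj
  G
}

#' Simulate case/control status, age and sex under a logistic disease model
#'
#' Ages are drawn from the configured normal distribution (truncated at 18
#' years), sex is Bernoulli(0.5), and case status is Bernoulli with
#' `logit P(case_i) = beta0 + sum_j beta_true_j g_ij +
#'  gamma_age (age_i - mean age) + gamma_sex sex_i`.
#' The intercept `beta0` is calibrated by bisection so that the expected
#' case fraction over the simulated cohort equals `case_fraction_target`
#' within 1e-4.
#'
#' @param genotypes Complete genotype matrix from [simulate_genotypes()].
#' @param variants The matching variant table.
#' @param config A [sim_config()].
#' @param subpops Optional subpopulation labels carried into the table.
#' @return A `data.frame` (class `phenotype_table`) with columns
#'   `sample_id`, `status` (1 = case), `age`, `sex`, `subpop`; `beta0` is
#'   attached as an attribute.
#' @export
simulate_phenotypes <- function(genotypes, variants, config,
                                subpops = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (anyNA(genotypes))
    stop_config("genotypes must be complete (inject missingness afterwards)")
  set.seed(derive_seed(config$seed, 4L))
  n <- nrow(genotypes)
  mu <- config$age_distribution[["mean"]]
  sdev <- config$age_distribution[["sd"]]
  age <- stats::rnorm(n, mu, sdev)
  while (any(age < 18)) {           # truncate below at 18 years
    bad <- age < 18
    age[bad] <- stats::rnorm(sum(bad), mu, sdev)
  }
  sex <- stats::rbinom(n, 1L, 0.5)
  gamma <- config$covariate_effects
  eta0 <- as.numeric(genotypes %*% variants$beta_true) +
    gamma[["gamma_age"]] * (age - mean(age)) + gamma[["gamma_sex"]] * sex
  target <- config$case_fraction_target
  f <- function(b0) mean(stats::plogis(b0 + eta0)) - target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0)
    stop("simulate_phenotypes: intercept bisection cannot bracket the ",
         "target case fraction; effect sizes are too extreme ",
         sprintf("(f(%g)=%.3g, f(%g)=%.3g)", lo, f(lo), hi, f(hi)))
  b0 <- stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
  stopifnot(abs(f(b0)) < 1e-4)
  status <- stats::rbinom(n, 1L, stats::plogis(b0 + eta0))
  out <- data.frame(
    sample_id = rownames(genotypes),
    status = as.integer(status),
    age = age,
    sex = as.integer(sex),
    subpop = if (is.null(subpops)) rep(1L, n) else as.integer(subpops),
    stringsAsFactors = FALSE
  )
  attr(out, "beta0") <- b0
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Set genotype calls missing completely at random
#'
#' @param genotypes Genotype matrix.
#' @param rate Per-entry missingness probability in [0,1).
#' @param seed Integer seed.
#' @return The matrix with missing entries set to `NA`.
#' @export
inject_missingness <- function(genotypes, rate, seed) {
  if (!is_prop(rate, 0, 1, FALSE, TRUE))
    stop_config("missing rate must lie in [0,1)")
  if (rate == 0) return(genotypes)
  set.seed(derive_seed(seed, 5L))
  mask <- stats::runif(length(genotypes)) < rate
  genotypes[mask] <- NA
  genotypes
}

#' Simulate a complete dataset bundle
#'
#' Convenience wrapper running [sample_variants()], [assign_subpops()],
#' [simulate_genotypes()], [simulate_phenotypes()] and
#' [inject_missingness()] in order.
#'
#' @param config A [sim_config()].
#' @return A `dataset_bundle`: list with elements `genotypes`, `variants`,
#'   `phenotypes` (see [dataset_bundle()]).
#' @export
simulate_dataset <- function(config) {
  variants <- sample_variants(config)
  subpops <- assign_subpops(config)
  G <- simulate_genotypes(variants, subpops, config)
  pheno <- simulate_phenotypes(G, variants, config, subpops = subpops)
  attr(G, "subpop_freq") <- NULL   # diagnostic attr stays on direct calls only
  G <- inject_missingness(G, config$missing_rate, config$seed)
  dataset_bundle(G, variants, pheno)
}
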