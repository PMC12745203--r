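# Shared fixtures, all built in code at test time.

.fixture_env <- new.env(parent = emptyenv())

# Small end-to-end pipeline run shared by attribution/acceptance tests.
demo_pipeline <- function() {
  if (is.null(.fixture_env$demo)) {
    cfg <- default_config(seed = 101L, n_subjects = 900L, m_snps = 300L,
                          k_causal = 8L)
    .fixture_env$demo <- suppressWarnings(run_pipeline(cfg))
  }
  .fixture_env$demo
}

# Purely linear "network": flatten + one dense layer. Exercises the
# attribution machinery where a closed form exists.
linear_fit <- function(w, b = 0) {
  L <- length(w)
  model <- structure(list(
    layers = list(list(type = "flatten", L = L, C = 1L),
                  list(type = "dense", W = matrix(w, L, 1L), b = b)),
    input_len = L, spec = NULL), class = "cnn_model")
  structure(list(model = model, log = NULL, best_epoch = 0L, spec = NULL),
            class = "cnn_fit")
}

# Genotype column with exact genotype counts (g0, g1, g2), fixed order.
geno_col <- function(g0, g1, g2) rep(c(0L, 1L, 2L), c(g0, g1, g2))

# QC toy: six focal SNPs with known fates (one call-rate failure, one
# rare-MAF failure, one strong HWE failure, three clean) padded with clean
# filler SNPs so that single missing calls do not push per-sample call
# rates below the default sample threshold.
qc_toy_bundle <- function(fillers = 114L) {
  n <- 500L   # the HWE column's counts are tuned to this size
  set.seed(424242)
  clean_col <- function() stats::rbinom(n, 2L, 0.3)
  G <- cbind(
    snp_crfail = { g <- clean_col(); g[seq_len(round(0.4 * n))] <- NA; g },
    snp_rare   = c(1L, rep(0L, n - 1L)),            # MAF = 1/(2n) = 0.001
    snp_hwe    = geno_col(161L, 178L, 161L),        # chi2 ~ 41.5, p ~ 1e-10
    snp_ok1    = clean_col(),
    snp_ok2    = clean_col(),
    snp_ok3    = clean_col())
  for (j in seq_len(fillers))
    G <- cbind(G, clean_col())
  colnames(G)[-(1:6)] <- sprintf("fill%03d", seq_len(fillers))
  rownames(G) <- sprintf("S%04d", seq_len(n))
  variants <- data.frame(
    chrom = "1", pos = seq_len(ncol(G)) * 100L, snp_id = colnames(G),
    ref_allele = "A", alt_allele = "G", ancestral_maf = NA_real_,
    is_causal = NA, beta_true = NA_real_, annotation = NA_character_,
    stringsAsFactors = FALSE)
  dataset_bundle(G, variants, NULL)
}

# Dataset where one SNP fully determines status (linearly separable),
# plus a little genotype noise alongside.
separable_bundle <- function(n = 400L, noise_snps = 4L, seed = 7L) {
  set.seed(seed)
  status <- rep(c(0L, 1L), each = n / 2)
  G <- cbind(sig = ifelse(status == 1, 2L, 0L),
             matrix(stats::rbinom(n * noise_snps, 2L, 0.3), n, noise_snps))
  colnames(G) <- c("sig", paste0("noise", seq_len(noise_snps)))
  rownames(G) <- sprintf("S%04d", seq_len(n))
  ord <- sample.int(n)            # shuffle so splits are class-mixed
  G <- G[ord, , drop = FALSE]
  status <- status[ord]
  pheno <- data.frame(sample_id = rownames(G), status = status,
                      age = stats::rnorm(n, 50, 10),
                      sex = stats::rbinom(n, 1, 0.5), subpop = 1L,
                      stringsAsFactors = FALSE)
  variants <- data.frame(
    chrom = "1", pos = seq_len(ncol(G)) * 10L, snp_id = colnames(G),
    ref_allele = "A", alt_allele = "G", ancestral_maf = NA_real_,
    is_causal = c(TRUE, rep(FALSE, noise_snps)),
    beta_true = NA_real_, annotation = NA_character_,
    stringsAsFactors = FALSE)
  dataset_bundle(G, variants, pheno)
}
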