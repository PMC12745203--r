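#' QC threshold configuration
#'
#' Conventional GWAS defaults: SNP and sample call rate at least 0.95,
#' minor allele frequency at least 0.01, Hardy-Weinberg equilibrium p-value
#' in controls at least 1e-6. All thresholds overridable.
#'
#' @param snp_call_rate_min Minimum per-SNP call rate, [0,1].
#' @param sample_call_rate_min Minimum per-sample call rate, [0,1].
#' @param maf_min Minimum minor allele frequency, [0,1].
#' @param hwe_p_min Minimum HWE chi-square p-value (tested in controls), [0,1].
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(snp_call_rate_min = 0.95,
                      sample_call_rate_min = 0.95,
                      maf_min = 0.01,
                      hwe_p_min = 1e-6) {
  vals <- c(snp_call_rate_min, sample_call_rate_min, maf_min, hwe_p_min)
  if (any(vals < 0 | vals > 1))
    stop_config("qc thresholds must lie in [0,1]")
  structure(list(snp_call_rate_min = snp_call_rate_min,
                 sample_call_rate_min = sample_call_rate_min,
                 maf_min = maf_min,
                 hwe_p_min = hwe_p_min),
            class = "qc_config")
}

#' Minor allele frequency of one genotype column
#'
#' @param g Vector of dosages in {0,1,2,NA}.
#' @return `min(p, 1-p)` where `p` is the alt-allele frequency among
#'   non-missing calls. Monomorphic columns return 0.
#' @export
snp_maf <- function(g) {
  g <- g[!is.na(g)]
  if (!length(g)) stop("snp_maf: all calls missing; MAF undefined")
  p <- sum(g) / (2 * length(g))
  min(p, 1 - p)
}

#' Chi-square test for Hardy-Weinberg equilibrium
#'
#' One-degree-of-freedom chi-square of observed genotype counts against the
#' HWE-expected counts at the estimated allele frequency. Monomorphic SNPs
#' are untestable: `chi2 = 0`, `p = 1`, flagged via `monomorphic`.
#'
#' @param g0,g1,g2 Counts of dosage-0, dosage-1 and dosage-2 genotypes.
#' @return List with `chi2`, `p`, `monomorphic`.
#' @export
hwe_test <- function(g0, g1, g2) {
  n <- g0 + g1 + g2
  if (n < 1) stop("hwe_test: needs at least one genotype")
  p <- (g1 + 2 * g2) / (2 * n)   # alt allele frequency
  if (p == 0 || p == 1)
    return(list(chi2 = 0, p = 1, monomorphic = TRUE))
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((c(g0, g1, g2) - e)^2 / e)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       monomorphic = FALSE)
}

#' Apply genotype quality control to a dataset bundle
#'
#' Filters are applied in a fixed order, each against the survivors of the
#' previous step: (1) sample call rate, (2) SNP call rate, (3) MAF,
#' (4) HWE in controls (in all subjects when no phenotypes are present).
#' The report records every removal with its reason.
#'
#' @param bundle A [dataset_bundle()].
#' @param qc A [qc_config()].
#' @return List with elements `bundle` (filtered) and `report` (class
#'   `qc_report`: per-stage before/after counts and removal lists).
#' @export
apply_qc <- function(bundle, qc = qc_config()) {
  stopifnot(inherits(bundle, "dataset_bundle"), inherits(qc, "qc_config"))
  G <- bundle$genotypes
  report <- list(
    input = c(samples = nrow(G), snps = ncol(G)),
    removed_samples = list(), removed_snps = list(), stages = list())

  log_stage <- function(report, stage, n_samp, n_snp) {
    report$stages[[stage]] <- c(samples = n_samp, snps = n_snp)
    report
  }

  # 1. sample call rate
  cr_samp <- rowMeans(!is.na(G))
  drop_s <- cr_samp < qc$sample_call_rate_min
  report$removed_samples$call_rate <- rownames(G)[drop_s]
  G <- G[!drop_s, , drop = FALSE]
  report <- log_stage(report, "sample_call_rate", nrow(G), ncol(G))
  if (nrow(G) == 0)
    stop("apply_qc: all samples removed; review sample_call_rate_min")

  pheno <- bundle$phenotypes
  if (!is.null(pheno)) pheno <- pheno[!drop_s, , drop = FALSE]

  # 2. SNP call rate
  cr_snp <- colMeans(!is.na(G))
  drop1 <- cr_snp < qc$snp_call_rate_min
  report$removed_snps$call_rate <- colnames(G)[drop1]
  G <- G[, !drop1, drop = FALSE]
  report <- log_stage(report, "snp_call_rate", nrow(G), ncol(G))

  # 3. MAF
  if (ncol(G)) {
    mafs <- apply(G, 2, snp_maf)
    drop2 <- mafs < qc$maf_min
    report$removed_snps$maf <- colnames(G)[drop2]
    G <- G[, !drop2, drop = FALSE]
  } else report$removed_snps$maf <- character(0)
  report <- log_stage(report, "maf", nrow(G), ncol(G))

  # 4. HWE in controls
  if (ncol(G)) {
    rows <- if (!is.null(pheno)) pheno$status == 0 else rep(TRUE, nrow(G))
    hwe_p <- apply(G[rows, , drop = FALSE], 2, function(g) {
      g <- g[!is.na(g)]
      hwe_test(sum(g == 0), sum(g == 1), sum(g == 2))$p
    })
    drop3 <- hwe_p < qc$hwe_p_min
    report$removed_snps$hwe <- colnames(G)[drop3]
    G <- G[, !drop3, drop = FALSE]
  } else report$removed_snps$hwe <- character(0)
  report <- log_stage(report, "hwe", nrow(G), ncol(G))

  if (ncol(G) == 0)
    stop("apply_qc: all SNPs removed; review QC thresholds")

  variants <- bundle$variants[bundle$variants$snp_id %in% colnames(G), ,
                              drop = FALSE]
  rownames(variants) <- NULL
  report$output <- c(samples = nrow(G), snps = ncol(G))
  class(report) <- "qc_report"
  list(bundle = dataset_bundle(G, variants, pheno), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> input %d samples x %d SNPs -> output %d x %d\n",
              x$input["samples"], x$input["snps"],
              x$output["samples"], x$output["snps"]))
  for (r in names(x$removed_samples))
    cat(sprintf("  samples removed (%s): %d\n", r,
                length(x$removed_samples[[r]])))
  for (r in names(x$removed_snps))
    cat(sprintf("  SNPs removed (%s): %d\n", r, length(x$removed_snps[[r]])))
  invisible(x)
}

#' Serialize a QC report as JSON
#' @param report A `qc_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Replace residual missing genotypes by the per-SNP mean dosage
#'
#' @param genotypes Post-QC genotype matrix (no all-missing columns).
#' @return Numeric matrix with no missing entries; imputed values are real
#'   numbers (mean dosage among the non-missing calls of that SNP).
#' @export
impute_missing <- function(genotypes) {
  if (!anyNA(genotypes)) return(genotypes)
  G <- genotypes * 1.0
  mu <- colMeans(G, na.rm = TRUE)
  idx <- which(is.na(G), arr.ind = TRUE)
  G[idx] <- mu[idx[, 2]]
  G
}
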