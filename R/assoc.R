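#' Genotype principal components for stratification adjustment
#'
#' Standardizes each SNP column to `(g - 2 p) / sqrt(2 p (1 - p))` with `p`
#' the sample alt-allele frequency (monomorphic SNPs are dropped from the
#' PCA input), then extracts the top-`k` principal-component scores per
#' subject from the eigendecomposition of the SNP-SNP covariance. The sign
#' of each component is fixed by making its largest-magnitude SNP loading
#' positive, so results are fully deterministic.
#'
#' @param genotypes Complete (imputed) genotype matrix, subjects x SNPs.
#' @param k Number of components (`>= 1`, at most the matrix rank).
#' @return Matrix `n x k` of PC scores (columns `pc1`, `pc2`, ...), with
#'   eigenvalues attached as attribute `eigenvalues` (all of them, for
#'   diagnostics).
#' @export
compute_pcs <- function(genotypes, k = 2L) {
  if (anyNA(genotypes)) stop_config("compute_pcs needs a complete matrix")
  if (!is_count(k)) stop_config("k must be a positive count")
  p <- colMeans(genotypes) / 2
  keep <- p > 0 & p < 1
  X <- genotypes[, keep, drop = FALSE]
  p <- p[keep]
  X <- sweep(X, 2, 2 * p, "-")
  X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  ev <- eigen(crossprod(X), symmetric = TRUE)
  rank <- sum(ev$values > max(ev$values) * 1e-9)
  if (k > rank) stop_config("k = ", k, " exceeds the matrix rank (", rank, ")")
  V <- ev$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- X %*% V
  colnames(scores) <- paste0("pc", seq_len(k))
  rownames(scores) <- rownames(genotypes)
  attr(scores, "eigenvalues") <- ev$values / (nrow(X) - 1)
  scores
}

#' Build the covariate table used by the association scan
#'
#' Centered age, sex and the top two genotype principal components.
#'
#' @param phenotypes A phenotype table.
#' @param pcs PC score matrix from [compute_pcs()] (or `NULL` for none).
#' @return Numeric covariate matrix aligned with the phenotype rows.
#' @export
covariate_table <- function(phenotypes, pcs = NULL) {
  cv <- cbind(age = phenotypes$age - mean(phenotypes$age),
              sex = phenotypes$sex)
  if (!is.null(pcs)) cv <- cbind(cv, pcs)
  rownames(cv) <- phenotypes$sample_id
  cv
}

# One SNP fit: logistic IRLS via glm.fit; returns beta, se and flags.
fit_snp_logistic <- function(g, y, covs, max_iter = 50L, tol = 1e-10) {
  X <- cbind(`(Intercept)` = 1, g = g, covs)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = tol,
                                                maxit = max_iter)))
  rank <- fit$rank
  if (rank < ncol(X) || !fit$converged) {
    # genotype column aliased (monomorphic) or IRLS did not converge
    aliased <- rank < ncol(X)
    return(c(beta = NA_real_, se = NA_real_, converged = !aliased && FALSE,
             separated = FALSE))
  }
  beta <- fit$coefficients
  # Wald SE from the observed information evaluated at the final
  # coefficients (glm.fit's QR carries the penultimate iteration's weights)
  pr <- stats::plogis(drop(X %*% beta))
  info <- crossprod(X, X * (pr * (1 - pr)))
  se <- sqrt(diag(solve(info)))
  # quasi-complete separation heuristic: runaway estimate or exploding SE
  separated <- abs(beta[2]) > 15 || se[2] > 100
  c(beta = unname(beta[2]), se = unname(se[2]),
    converged = TRUE, separated = separated)
}

#' Per-SNP covariate-adjusted logistic association scan
#'
#' For each SNP independently, fits
#' `logit P(case) = alpha + beta_j g_j + gamma' (age, sex, pc1, pc2)`
#' by iteratively reweighted least squares (base R's `glm.fit`, max 50
#' iterations) and reports the per-alt-allele log odds ratio, its standard
#' error, the Wald statistic `z = beta / se` and the two-sided normal
#' p-value. Monomorphic SNPs, non-converged fits and quasi-complete
#' separation are flagged and get `p = NaN` (never entering threshold
#' subsets).
#'
#' @param genotypes Complete genotype matrix.
#' @param phenotypes Phenotype table (status 0/1) aligned with rows.
#' @param covariates Covariate matrix from [covariate_table()].
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return A `data.frame` (class `assoc_result`): `snp_id`, `chrom`, `pos`,
#'   `beta`, `se`, `z`, `p`, `converged`, `separation_flag`.
#' @param variants Optional variant table supplying `chrom`/`pos`.
#' @export
logistic_scan <- function(genotypes, phenotypes, covariates,
                          variants = NULL, max_iter = 50L, tol = 1e-10) {
  if (anyNA(genotypes)) stop_config("logistic_scan needs a complete matrix")
  y <- phenotypes$status
  if (!identical(phenotypes$sample_id, rownames(genotypes)))
    stop_config("phenotypes are not aligned with genotype rows")
  m <- ncol(genotypes)
  res <- matrix(NA_real_, m, 4L,
                dimnames = list(NULL, c("beta", "se", "converged", "separated")))
  for (j in seq_len(m)) {
    g <- genotypes[, j]
    if (stats::var(g) == 0) {
      res[j, ] <- c(NA, NA, 0, 0)   # monomorphic
      next
    }
    res[j, ] <- fit_snp_logistic(g, y, covariates, max_iter, tol)
  }
  z <- res[, "beta"] / res[, "se"]
  p <- 2 * stats::pnorm(-abs(z))
  bad <- res[, "converged"] == 0 | res[, "separated"] == 1 | is.na(z)
  p[bad] <- NaN
  z[bad] <- NaN
  out <- data.frame(
    snp_id = colnames(genotypes),
    chrom = if (!is.null(variants)) variants$chrom else NA_character_,
    pos = if (!is.null(variants)) variants$pos else seq_len(m),
    beta = res[, "beta"],
    se = res[, "se"],
    z = z,
    p = p,
    converged = res[, "converged"] == 1,
    separation_flag = res[, "separated"] == 1,
    stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Build nested p-value-threshold SNP subsets
#'
#' Strict inequality `p < tau`; `NaN`/`NA` p-values are never selected.
#' Subsets are nested by construction and listed in genomic order.
#'
#' @param assoc An [logistic_scan()] result (rows already in genomic order).
#' @param thresholds Numeric vector of thresholds; default the conventional
#'   ladder 5e-2 ... 5e-8.
#' @return Named list (names are the threshold values as written, e.g.
#'   `"5e-04"`) of SNP id vectors; class `threshold_subsets`.
#' @export
select_snp_subsets <- function(assoc,
                               thresholds = c(5e-2, 5e-3, 5e-4, 5e-5,
                                              5e-6, 5e-7, 5e-8)) {
  thresholds <- sort(thresholds, decreasing = TRUE)
  p <- assoc$p
  out <- lapply(thresholds, function(tau) {
    sel <- !is.na(p) & !is.nan(p) & p < tau
    assoc$snp_id[sel]
  })
  names(out) <- format(thresholds, scientific = TRUE, trim = TRUE)
  empty <- vapply(out, length, integer(1)) == 0L
  if (any(empty))
    warning("empty SNP subset at threshold(s): ",
            paste(names(out)[empty], collapse = ", "),
            "; downstream training will skip them", call. = FALSE)
  class(out) <- c("threshold_subsets", "list")
  out
}
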