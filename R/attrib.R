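# Deep SHAP attributions for the CNN: DeepLIFT-style multipliers propagated
# from the pre-sigmoid (logit) output to the SNP inputs, once per background
# reference, then averaged over the background set.
#
# Propagation rules: linear rule for conv/dense/average-pool/flatten
# (identical to the gradient), rescale rule for ReLU
# (multiplier = delta-activation / delta-preactivation). Dropout is
# identity at inference. Because every non-ReLU layer is linear and the
# rescale rule conserves deltas exactly, the completeness identity
# sum_j phi_ij = f(x_i) - f(b) holds to float precision per reference.

# Multiplier backward pass for one background reference.
# cache_x / cache_r: caches from cnn_forward() on inputs and on the (single
# row) reference. Returns an n x L matrix of multipliers at the input.
deeplift_multipliers <- function(model, cache_x, cache_r, n) {
  M <- matrix(1, n, 1L)   # d(logit)/d(logit)
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    if (ly$type == "dense") {
      M <- M %*% t(ly$W)
    } else if (ly$type == "dropout") {
      # identity at inference
    } else if (ly$type == "relu") {
      zx <- cache_x[[i]]$z
      zr <- cache_r[[i]]$z          # dims (1, ...) -> broadcast below
      dz <- sweep_minus(zx, zr)
      da <- sweep_minus(pmax(zx, 0), pmax(zr, 0))
      ratio <- ifelse(abs(dz) > 1e-9, da / dz, (zx > 0) * 1)
      M <- M * ratio
    } else if (ly$type == "flatten") {
      M <- array(M, cache_x[[i]]$in_dim)
    } else if (ly$type == "avgpool") {
      M <- pool_bwd(M, cache_x[[i]]$in_dim, ly$w)
    } else if (ly$type == "conv") {
      M <- conv_bwd(M, array(0, cache_x[[i]]$in_dim),
                    cache_x[[i]]$patches, ly)$dA
    }
  }
  matrix(M, n, dim(M)[2])   # input channel dim is 1
}

# x - r where r has one "subject" row: broadcast over the first dim.
sweep_minus <- function(x, r) {
  if (is.matrix(x)) return(sweep(x, 2, as.numeric(r), "-"))
  d <- dim(x)
  x - array(rep(as.numeric(r), each = d[1]), d)
}

#' Deep SHAP attributions for a fitted CNN
#'
#' For each background reference `b`, DeepLIFT multipliers are propagated
#' from the model's pre-sigmoid output to the inputs (rescale rule at ReLU,
#' linear rule elsewhere), giving per-reference attributions
#' `phi^(b)_ij = m_ij (x_ij - b_j)` with
#' `sum_j phi^(b)_ij = f(x_i) - f(b)` exactly. Attributions are averaged
#' over the background set; the completeness identity against
#' `baseline = mean_b f(b)` is asserted to 1e-4 for every subject.
#'
#' @param fit A `cnn_fit` from [train_classifier()].
#' @param x Encoded inputs to attribute (subjects x SNPs), typically the
#'   test split.
#' @param background Encoded background matrix (rows drawn from the
#'   training split; both classes).
#' @return Object of class `attribution_matrix`: `phi` (subjects x SNPs,
#'   logit units), `baseline_value`, `background_size`, `unit`.
#' @export
compute_attributions <- function(fit, x, background) {
  stopifnot(inherits(fit, "cnn_fit"), is.matrix(x), is.matrix(background),
            ncol(x) == ncol(background))
  model <- fit$model
  off <- fit$logit_offset %||% 0    # constant shift; cancels in the deltas
  n <- nrow(x)
  fx <- cnn_forward(model, x)
  phi <- matrix(0, n, ncol(x), dimnames = dimnames(x))
  fb <- numeric(nrow(background))
  for (b in seq_len(nrow(background))) {
    br <- background[b, , drop = FALSE]
    fr <- cnn_forward(model, br)
    fb[b] <- fr$logit
    M <- deeplift_multipliers(model, fx$caches, fr$caches, n)
    phi <- phi + M * sweep(x, 2, as.numeric(br), "-")
  }
  phi <- phi / nrow(background)
  baseline <- mean(fb) + off
  gap <- abs(rowSums(phi) - (fx$logit + off - baseline))
  if (any(gap > 1e-4))
    stop("compute_attributions: completeness violated (max |gap| = ",
         format(max(gap)), "); an unsupported layer type may be present")
  structure(list(phi = phi, baseline_value = baseline,
                 background_size = nrow(background), unit = "logit"),
            class = "attribution_matrix")
}

#' Draw a background set from the training split
#'
#' Uniform sample (both classes) of encoded training rows; seed-controlled.
#'
#' @param x_train Encoded training matrix.
#' @param size Background size (capped at `nrow(x_train)`).
#' @param seed Integer seed.
#' @return Matrix of background rows.
#' @export
sample_background <- function(x_train, size = 100L, seed = 1L) {
  set.seed(derive_seed(seed, 30L))
  x_train[sample.int(nrow(x_train), min(size, nrow(x_train))), ,
          drop = FALSE]
}

#' Aggregate attributions into per-SNP contribution scores
#'
#' The aggregation set S holds the test subjects whose true label is case
#' and whose predicted case probability reaches the decision threshold
#' (true positives). The contribution score of SNP j is the mean absolute
#' attribution over S: `C_j = mean_{i in S} |phi_ij|`. Ranks are assigned
#' in descending score order with ties broken by ascending association
#' p-value, then lexicographic SNP id.
#'
#' @param attrib An [compute_attributions()] result.
#' @param scores Predicted case probabilities aligned with `attrib$phi` rows.
#' @param labels True 0/1 labels, same alignment.
#' @param threshold Decision threshold (default 0.5).
#' @param assoc_p Optional named vector of association p-values used for
#'   tie-breaking (names = SNP ids).
#' @return A `data.frame` (class `contribution_table`): `snp_id`,
#'   `contribution`, `rank`, `n_aggregated` (+ `assoc_p` when supplied).
#' @export
contribution_scores <- function(attrib, scores, labels, threshold = 0.5,
                                assoc_p = NULL) {
  stopifnot(inherits(attrib, "attribution_matrix"),
            length(scores) == nrow(attrib$phi),
            length(labels) == nrow(attrib$phi))
  S <- labels == 1 & scores >= threshold
  if (!any(S))
    stop("contribution_scores: no correctly predicted cases at threshold ",
         threshold, "; inspect the model or lower the threshold")
  C <- colMeans(abs(attrib$phi[S, , drop = FALSE]))
  ids <- colnames(attrib$phi)
  pv <- if (!is.null(assoc_p)) unname(assoc_p[ids]) else rep(NA_real_, length(C))
  out <- data.frame(snp_id = ids, contribution = unname(C),
                    assoc_p = pv, n_aggregated = sum(S),
                    stringsAsFactors = FALSE)
  rank_snps(out)
}
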