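# 1-D convolutional case/control classifier, implemented directly in base R
# matrix code (no deep-learning framework). Layers: repeated
# [conv -> ReLU -> average-pool] blocks over the SNP axis, then
# flatten -> dense -> ReLU -> dropout -> dense(1) -> sigmoid.
#
# Average pooling (not max) is used so every layer except ReLU is linear;
# the DeepLIFT rescale attribution in attrib.R is then exact and the SHAP
# completeness identity holds to float precision.
#
# Internal activation layout: 3-D arrays [subject, position, channel].
# Convolutions are computed by patch extraction (im2col) + one matrix
# multiplication, so BLAS does the heavy lifting.

#' Classifier hyperparameter specification
#'
#' Defaults describe a small CNN: two conv blocks (16 then 32 filters,
#' kernel width 5, average-pool width 2), a 32-unit dense layer, dropout
#' 0.3, Adam with learning rate 1e-3, batch size 32, at most 200 epochs
#' with early stopping after 10 epochs without validation-loss improvement.
#' For inputs shorter than the kernel the effective kernel width shrinks to
#' the input length, and pooling is skipped when fewer than `pool_width`
#' positions remain, so very small SNP subsets (down to a single SNP)
#' remain trainable.
#'
#' @param conv_filters Integer vector, filters per conv block.
#' @param kernel_width Convolution kernel width, in SNP positions.
#' @param pool_width Average-pooling width (and stride).
#' @param dense_units Units in the dense hidden layer.
#' @param dropout Dropout rate in [0,1) applied after the dense ReLU.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param seed Integer seed controlling weight init, shuffling and dropout.
#' @return Object of class `cnn_spec`.
#' @export
cnn_spec <- function(conv_filters = c(16L, 32L), kernel_width = 5L,
                     pool_width = 2L, dense_units = 32L, dropout = 0.3,
                     learning_rate = 1e-3, batch_size = 32L,
                     max_epochs = 200L, patience = 10L, seed = 1L) {
  stopifnot(all(conv_filters >= 1), kernel_width >= 1, pool_width >= 1,
            dense_units >= 1, dropout >= 0, dropout < 1,
            learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1)
  structure(list(conv_filters = as.integer(conv_filters),
                 kernel_width = as.integer(kernel_width),
                 pool_width = as.integer(pool_width),
                 dense_units = as.integer(dense_units),
                 dropout = dropout, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "cnn_spec")
}

#' Stratified train/validation/test split
#'
#' Random assignment stratified by case status with largest-remainder
#' rounding, so per-split class fractions match the global fraction up to
#' integer rounding. Deterministic given the seed.
#'
#' @param phenotypes Phenotype table with `sample_id` and `status`.
#' @param fractions Length-3 numeric vector (train, validation, test)
#'   summing to 1.
#' @param seed Integer seed.
#' @return List of class `split_spec` with `train`, `val`, `test` sample-id
#'   vectors.
#' @export
split_dataset <- function(phenotypes, fractions = c(0.5, 0.25, 0.25),
                          seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9)
  counts <- table(phenotypes$status)
  if (length(counts) < 2L || any(counts < 8L))
    stop_config("split_dataset: need at least 8 samples per class to stratify")
  set.seed(derive_seed(seed, 10L))
  out <- list(train = character(0), val = character(0), test = character(0))
  for (cls in names(counts)) {
    ids <- phenotypes$sample_id[phenotypes$status == as.integer(cls)]
    ids <- sample(ids)
    n <- length(ids)
    quota <- n * fractions
    base <- floor(quota)
    rem <- quota - base
    extra <- n - sum(base)
    if (extra > 0) {
      give <- order(rem, decreasing = TRUE)[seq_len(extra)]
      base[give] <- base[give] + 1L
    }
    cuts <- cumsum(base)
    out$train <- c(out$train, ids[seq_len(base[1])])
    out$val <- c(out$val, ids[(cuts[1] + 1):cuts[2]])
    out$test <- c(out$test, ids[(cuts[2] + 1):cuts[3]])
  }
  structure(list(train = out$train, val = out$val, test = out$test,
                 fractions = fractions, seed = as.integer(seed)),
            class = "split_spec")
}

#' Standardize genotype dosages with training-split statistics
#'
#' Per-SNP mean/sd are computed on the training rows only and applied
#' unchanged to validation/test rows (no leakage). SNPs with zero training
#' variance are dropped with a warning and recorded.
#'
#' @param genotypes Complete dosage matrix (all subjects), SNPs ordered by
#'   genomic position.
#' @param train_ids Sample ids of the training split.
#' @return List of class `geno_encoder`: `center`, `scale`, `snp_ids`
#'   (kept SNPs), `dropped`. Apply with [encode_genotypes()].
#' @export
fit_encoder <- function(genotypes, train_ids) {
  tr <- genotypes[train_ids, , drop = FALSE]
  mu <- colMeans(tr)
  sdev <- apply(tr, 2, stats::sd)
  drop <- sdev == 0 | is.na(sdev)
  if (any(drop))
    warning(sum(drop), " zero-variance SNP(s) in training split dropped: ",
            paste(utils::head(colnames(genotypes)[drop], 5), collapse = ", "),
            if (sum(drop) > 5) ", ..." else "", call. = FALSE)
  structure(list(center = mu[!drop], scale = sdev[!drop],
                 snp_ids = colnames(genotypes)[!drop],
                 dropped = colnames(genotypes)[drop]),
            class = "geno_encoder")
}

#' @rdname fit_encoder
#' @param encoder A fitted `geno_encoder`.
#' @param genotypes Dosage matrix to encode (any split).
#' @return Standardized numeric matrix, subjects x kept SNPs (the model
#'   input block; the trailing channel axis of size 1 is implicit).
#' @export
encode_genotypes <- function(encoder, genotypes) {
  stopifnot(inherits(encoder, "geno_encoder"))
  X <- genotypes[, encoder$snp_ids, drop = FALSE]
  X <- sweep(X, 2, encoder$center, "-")
  sweep(X, 2, encoder$scale, "/")
}

# ---- architecture -------------------------------------------------------

# Build layer list for input length L (channels start at 1).
build_cnn <- function(spec, input_len) {
  L <- as.integer(input_len); C <- 1L
  if (L < 1) stop_config("build_cnn: empty input")
  layers <- list()
  for (f in spec$conv_filters) {
    k <- min(spec$kernel_width, L)
    fan_in <- k * C
    W <- matrix(stats::rnorm(fan_in * f, 0, sqrt(2 / fan_in)), fan_in, f)
    layers[[length(layers) + 1L]] <- list(type = "conv", k = k, Cin = C,
                                          Fout = f, W = W, b = numeric(f))
    L <- L - k + 1L; C <- f
    layers[[length(layers) + 1L]] <- list(type = "relu")
    if (L >= spec$pool_width && L > 1L) {
      layers[[length(layers) + 1L]] <- list(type = "avgpool",
                                            w = spec$pool_width)
      L <- L %/% spec$pool_width
    }
  }
  layers[[length(layers) + 1L]] <- list(type = "flatten", L = L, C = C)
  D <- L * C
  W <- matrix(stats::rnorm(D * spec$dense_units, 0, sqrt(2 / D)),
              D, spec$dense_units)
  layers[[length(layers) + 1L]] <- list(type = "dense", W = W,
                                        b = numeric(spec$dense_units))
  layers[[length(layers) + 1L]] <- list(type = "relu")
  layers[[length(layers) + 1L]] <- list(type = "dropout", p = spec$dropout)
  W <- matrix(stats::rnorm(spec$dense_units, 0, sqrt(1 / spec$dense_units)),
              spec$dense_units, 1L)
  layers[[length(layers) + 1L]] <- list(type = "dense", W = W, b = 0)
  structure(list(layers = layers, input_len = as.integer(input_len),
                 spec = spec), class = "cnn_model")
}

# im2col patch extraction: A [n,L,C] -> matrix [n*P, k*C], P = L-k+1.
im2col <- function(A, k) {
  n <- dim(A)[1]; L <- dim(A)[2]; C <- dim(A)[3]
  P <- L - k + 1L
  Xc <- array(0, c(n, P, k * C))
  for (t in seq_len(P))
    Xc[, t, ] <- A[, t:(t + k - 1L), , drop = FALSE]
  list(mat = matrix(Xc, n * P, k * C), n = n, P = P)
}

conv_fwd <- function(A, layer) {
  ic <- im2col(A, layer$k)
  Y <- ic$mat %*% layer$W
  Y <- sweep(Y, 2, layer$b, "+")
  list(out = array(Y, c(ic$n, ic$P, layer$Fout)), patches = ic$mat)
}

conv_bwd <- function(dY, A, patches, layer) {
  n <- dim(dY)[1]; P <- dim(dY)[2]
  dYm <- matrix(dY, n * P, layer$Fout)
  dW <- crossprod(patches, dYm)
  db <- colSums(dYm)
  dXc <- array(dYm %*% t(layer$W), c(n, P, layer$k * dim(A)[3]))
  dA <- array(0, dim(A))
  k <- layer$k; C <- dim(A)[3]
  for (t in seq_len(P))
    dA[, t:(t + k - 1L), ] <- dA[, t:(t + k - 1L), , drop = FALSE] +
      array(dXc[, t, ], c(n, k, C))
  list(dA = dA, dW = dW, db = db)
}

pool_fwd <- function(A, w) {
  n <- dim(A)[1]; L <- dim(A)[2]; C <- dim(A)[3]
  P <- L %/% w
  Y <- array(0, c(n, P, C))
  for (u in seq_len(P)) {
    acc <- A[, (u - 1L) * w + 1L, , drop = FALSE]
    for (j in 2:w)
      acc <- acc + A[, (u - 1L) * w + j, , drop = FALSE]
    Y[, u, ] <- acc / w
  }
  Y
}

pool_bwd <- function(dY, in_dim, w) {
  n <- in_dim[1]; L <- in_dim[2]; C <- in_dim[3]
  P <- dim(dY)[2]
  dA <- array(0, in_dim)
  for (u in seq_len(P))
    for (j in seq_len(w))
      dA[, (u - 1L) * w + j, ] <- dY[, u, ] / w
  dA
}

# Forward pass. X: n x L matrix. Returns logits and per-layer caches.
cnn_forward <- function(model, X, training = FALSE) {
  n <- nrow(X)
  A <- array(X, c(n, ncol(X), 1L))
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$type == "conv") {
      cf <- conv_fwd(A, ly)
      caches[[i]] <- list(in_dim = dim(A), patches = cf$patches)
      A <- cf$out
    } else if (ly$type == "relu") {
      caches[[i]] <- list(z = A)
      A <- pmax(A, 0)
    } else if (ly$type == "avgpool") {
      caches[[i]] <- list(in_dim = dim(A))
      A <- pool_fwd(A, ly$w)
    } else if (ly$type == "flatten") {
      caches[[i]] <- list(in_dim = dim(A))
      A <- matrix(A, n, ly$L * ly$C)
    } else if (ly$type == "dense") {
      caches[[i]] <- list(a_in = A)
      A <- sweep(A %*% ly$W, 2, ly$b, "+")
    } else if (ly$type == "dropout") {
      if (training && ly$p > 0) {
        mask <- matrix(stats::rbinom(length(A), 1L, 1 - ly$p) / (1 - ly$p),
                       nrow(A), ncol(A))
        caches[[i]] <- list(mask = mask)
        A <- A * mask
      } else caches[[i]] <- list(mask = NULL)
    }
  }
  list(logit = as.numeric(A), caches = caches)
}

# Backward pass from d(loss)/d(logit); returns gradients per layer.
cnn_backward <- function(model, dlogit, caches) {
  grads <- vector("list", length(model$layers))
  dA <- matrix(dlogit, length(dlogit), 1L)
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    ch <- caches[[i]]
    if (ly$type == "dense") {
      grads[[i]] <- list(dW = crossprod(ch$a_in, dA), db = colSums(dA))
      dA <- dA %*% t(ly$W)
    } else if (ly$type == "dropout") {
      if (!is.null(ch$mask)) dA <- dA * ch$mask
    } else if (ly$type == "relu") {
      dA <- dA * (ch$z > 0)
    } else if (ly$type == "flatten") {
      dA <- array(dA, ch$in_dim)
    } else if (ly$type == "avgpool") {
      dA <- pool_bwd(dA, ch$in_dim, ly$w)
    } else if (ly$type == "conv") {
      A_in_dim <- ch$in_dim
      cb <- conv_bwd(dA, array(0, A_in_dim), ch$patches, ly)
      grads[[i]] <- list(dW = cb$dW, db = cb$db)
      dA <- cb$dA
    }
  }
  grads
}

weighted_bce <- function(logit, y, w) {
  # numerically stable: log(1+exp(-|z|)) form
  z <- logit
  nll <- pmax(z, 0) - z * y + log1p(exp(-abs(z)))
  mean(w * nll)
}

#' Train the convolutional classifier
#'
#' Minimizes class-weighted binary cross-entropy (weights inversely
#' proportional to class frequency in the training split) with Adam,
#' shuffled minibatches, and early stopping on validation loss; the weights
#' of the best validation epoch are restored. Fully deterministic given the
#' spec seed.
#'
#' @param x_train,y_train Encoded training inputs (subjects x SNPs) and 0/1
#'   labels.
#' @param x_val,y_val Validation split, same encoding.
#' @param spec A [cnn_spec()].
#' @return Object of class `cnn_fit`: the model, the training `log`
#'   (epoch, train loss, validation loss/accuracy) and `best_epoch`.
#' @export
train_classifier <- function(x_train, y_train, x_val, y_val, spec) {
  stopifnot(inherits(spec, "cnn_spec"), nrow(x_train) == length(y_train),
            nrow(x_val) == length(y_val), ncol(x_train) >= 1)
  set.seed(derive_seed(spec$seed, 20L))
  model <- build_cnn(spec, ncol(x_train))
  n <- nrow(x_train)
  n1 <- sum(y_train == 1); n0 <- n - n1
  if (n1 == 0 || n0 == 0) stop_config("training split has a single class")
  cw <- ifelse(y_train == 1, n / (2 * n1), n / (2 * n0))
  # class-weighted training calibrates the output to a balanced prevalence;
  # this intercept correction restores natural-prevalence probabilities so
  # the 0.5 decision threshold keeps its usual meaning (prior correction)
  logit_offset <- log(n1 / n0)
  cw_val <- ifelse(y_val == 1,
                   length(y_val) / (2 * sum(y_val == 1)),
                   length(y_val) / (2 * sum(y_val == 0)))
  # Adam state mirrors the layer list
  mstate <- lapply(model$layers, function(ly)
    if (!is.null(ly$W)) list(mW = ly$W * 0, vW = ly$W * 0,
                             mb = ly$b * 0, vb = ly$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_step <- 0
  lr <- spec$learning_rate
  best <- list(loss = Inf, layers = model$layers, epoch = 0L)
  stall <- 0L
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0), val_acc = numeric(0))
  for (epoch in seq_len(spec$max_epochs)) {
    idx <- sample.int(n)
    nb <- ceiling(n / spec$batch_size)
    tr_loss <- 0
    for (bi in seq_len(nb)) {
      rows <- idx[((bi - 1L) * spec$batch_size + 1L):min(bi * spec$batch_size, n)]
      fw <- cnn_forward(model, x_train[rows, , drop = FALSE], training = TRUE)
      if (any(!is.finite(fw$logit)))
        stop("train_classifier: divergence (non-finite logits) at epoch ",
             epoch, "; best checkpoint was epoch ", best$epoch)
      yb <- y_train[rows]; wb <- cw[rows]
      pb <- stats::plogis(fw$logit)
      tr_loss <- tr_loss + weighted_bce(fw$logit, yb, wb) * length(rows)
      dlogit <- wb * (pb - yb) / length(rows)
      grads <- cnn_backward(model, dlogit, fw$caches)
      t_step <- t_step + 1
      corr <- sqrt(1 - b2^t_step) / (1 - b1^t_step)
      for (i in seq_along(model$layers)) {
        if (is.null(grads[[i]])) next
        st <- mstate[[i]]
        st$mW <- b1 * st$mW + (1 - b1) * grads[[i]]$dW
        st$vW <- b2 * st$vW + (1 - b2) * grads[[i]]$dW^2
        model$layers[[i]]$W <- model$layers[[i]]$W -
          lr * corr * st$mW / (sqrt(st$vW) + eps)
        st$mb <- b1 * st$mb + (1 - b1) * grads[[i]]$db
        st$vb <- b2 * st$vb + (1 - b2) * grads[[i]]$db^2
        model$layers[[i]]$b <- model$layers[[i]]$b -
          lr * corr * st$mb / (sqrt(st$vb) + eps)
        mstate[[i]] <- st
      }
    }
    val_logit <- cnn_forward(model, x_val)$logit
    val_loss <- weighted_bce(val_logit, y_val, cw_val)
    val_acc <- mean((val_logit + logit_offset >= 0) == (y_val == 1))
    log <- rbind(log, data.frame(epoch = epoch, train_loss = tr_loss / n,
                                 val_loss = val_loss, val_acc = val_acc))
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, layers = model$layers, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= spec$patience) break
    }
  }
  model$layers <- best$layers
  structure(list(model = model, log = log, best_epoch = best$epoch,
                 logit_offset = logit_offset, spec = spec),
            class = "cnn_fit")
}

#' Predict case probabilities
#'
#' Predictions are prior-corrected: because training uses class-weighted
#' loss (balanced effective prevalence), the raw network output is shifted
#' by `log(n_case/n_control)` of the training split so probabilities refer
#' to the natural cohort prevalence and the 0.5 threshold keeps its usual
#' meaning.
#'
#' @param object A `cnn_fit` from [train_classifier()].
#' @param x Encoded input matrix.
#' @param type `"prob"` (default) or `"logit"` (natural-prevalence logit).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.cnn_fit <- function(object, x, type = c("prob", "logit"), ...) {
  type <- match.arg(type)
  z <- cnn_forward(object$model, x)$logit + (object$logit_offset %||% 0)
  if (type == "logit") z else stats::plogis(z)
}

#' Rank-based AUC (Mann-Whitney, ties counted 0.5)
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUC in [0,1].
#' @export
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("auc_rank: AUC undefined for a single-class set")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary classification metrics report
#'
#' Computes sensitivity, specificity, accuracy, AUC (rank statistic with
#' ties counted 0.5) and the diagnostic odds ratio
#' `(TP * TN) / (FP * FN)`; when any confusion cell is zero a +0.5
#' continuity correction is added to every cell and the report is flagged.
#'
#' @param scores Predicted case probabilities.
#' @param labels True 0/1 labels.
#' @param threshold Decision threshold: case iff `score >= threshold`.
#' @param split Optional split label carried into the report.
#' @return List of class `metrics_report`: `se`, `sp`, `acc`, `auc`, `or_`,
#'   `confusion` (TP, FP, TN, FN), `or_corrected`, `split`.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5,
                                   split = NULL) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  corrected <- any(c(tp, fp, tn, fn) == 0)
  cc <- if (corrected) 0.5 else 0
  structure(list(
    se = tp / (tp + fn),
    sp = tn / (tn + fp),
    acc = (tp + tn) / (tp + fp + tn + fn),
    auc = auc_rank(scores, labels),
    or_ = ((tp + cc) * (tn + cc)) / ((fp + cc) * (fn + cc)),
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
    or_corrected = corrected,
    split = split), class = "metrics_report")
}

#' Train one classifier per threshold subset and select the best
#'
#' Trains the CNN on each non-empty p-value-threshold subset using
#' identical splits and seed, picks the winner by validation accuracy
#' (ties broken toward the smaller SNP subset), and evaluates test metrics
#' for the winner only.
#'
#' @param genotypes Complete (imputed) dosage matrix, SNPs in genomic order.
#' @param phenotypes Phenotype table.
#' @param subsets A [select_snp_subsets()] result.
#' @param splits A [split_dataset()] result.
#' @param spec A [cnn_spec()].
#' @param threshold Decision threshold for the metrics.
#' @return List of class `model_selection`: `best_tau`, `fit` (winner),
#'   `encoder`, `val_metrics_by_tau` (data.frame), `test_metrics`
#'   (winner only), `test_scores`, `test_ids`.
#' @export
select_best_model <- function(genotypes, phenotypes, subsets, splits, spec,
                              threshold = 0.5) {
  stopifnot(inherits(subsets, "threshold_subsets"))
  sizes <- vapply(subsets, length, integer(1))
  if (all(sizes == 0L)) stop("select_best_model: all SNP subsets are empty")
  status <- stats::setNames(phenotypes$status, phenotypes$sample_id)
  rows <- list()
  fits <- list()
  for (tau in names(subsets)) {
    ids <- subsets[[tau]]
    if (!length(ids)) {
      warning("skipping empty subset at tau = ", tau, call. = FALSE)
      next
    }
    enc <- fit_encoder(genotypes[, ids, drop = FALSE], splits$train)
    if (!length(enc$snp_ids)) {
      warning("skipping subset at tau = ", tau,
              ": all SNPs constant in training split", call. = FALSE)
      next
    }
    x_tr <- encode_genotypes(enc, genotypes[splits$train, , drop = FALSE])
    x_va <- encode_genotypes(enc, genotypes[splits$val, , drop = FALSE])
    fit <- train_classifier(x_tr, status[splits$train],
                            x_va, status[splits$val], spec)
    val_scores <- predict(fit, x_va)
    vm <- classification_metrics(val_scores, status[splits$val],
                                 threshold, split = "validation")
    rows[[tau]] <- data.frame(tau = tau, n_snps = length(enc$snp_ids),
                              val_acc = vm$acc, val_auc = vm$auc,
                              stringsAsFactors = FALSE)
    fits[[tau]] <- list(fit = fit, encoder = enc)
  }
  if (!length(fits)) stop("select_best_model: no trainable subset")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  # winner: highest validation accuracy, ties toward the smaller subset
  ord <- order(-tab$val_acc, tab$n_snps)
  best_tau <- tab$tau[ord[1]]
  winner <- fits[[best_tau]]
  x_te <- encode_genotypes(winner$encoder,
                           genotypes[splits$test, , drop = FALSE])
  test_scores <- predict(winner$fit, x_te)
  tm <- classification_metrics(test_scores, status[splits$test],
                               threshold, split = "test")
  structure(list(best_tau = best_tau, fit = winner$fit,
                 encoder = winner$encoder, val_metrics_by_tau = tab,
                 test_metrics = tm, test_scores = test_scores,
                 test_ids = splits$test), class = "model_selection")
}
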