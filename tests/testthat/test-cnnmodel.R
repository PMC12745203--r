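test_that("stratified split hits exact fractions and stays deterministic", {
  ph <- data.frame(sample_id = sprintf("P%03d", 1:200),
                   status = rep(c(1L, 0L), each = 100),
                   stringsAsFactors = FALSE)
  sp <- split_dataset(ph, seed = 4)
  st <- setNames(ph$status, ph$sample_id)
  for (cls in 0:1) {
    expect_equal(sum(st[sp$train] == cls), 50)
    expect_equal(sum(st[sp$val] == cls), 25)
    expect_equal(sum(st[sp$test] == cls), 25)
  }
  expect_setequal(c(sp$train, sp$val, sp$test), ph$sample_id)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(split_dataset(ph, seed = 4), split_dataset(ph, seed = 4))
})

test_that("largest-remainder split of a 750/3500 cohort rounds as expected", {
  ph <- data.frame(sample_id = sprintf("P%04d", 1:4250),
                   status = rep(c(1L, 0L), c(750, 3500)),
                   stringsAsFactors = FALSE)
  sp <- split_dataset(ph, seed = 99)
  st <- setNames(ph$status, ph$sample_id)
  expect_equal(sum(st[sp$train] == 1), 375)
  expect_true(sum(st[sp$test] == 1) %in% c(187, 188))
  expect_equal(sum(st[sp$test] == 0), 875)
  # per-split case fraction within 2 points of global (17.6%)
  for (s in list(sp$train, sp$val, sp$test))
    expect_lt(abs(mean(st[s]) - 750 / 4250), 0.02)
})

test_that("encoder standardizes on training statistics only", {
  G <- rbind(tr1 = c(0.5, 1), tr2 = c(1.5, 1), te = c(2, 1))
  colnames(G) <- c("a", "b")
  expect_warning(enc <- fit_encoder(G, c("tr1", "tr2")), "zero-variance")
  expect_identical(enc$dropped, "b")
  X <- encode_genotypes(enc, G)
  expect_equal(X["te", "a"], (2 - 1) / sd(c(0.5, 1.5)))

  set.seed(2)
  G2 <- matrix(rbinom(300, 2, 0.4) * 1.0, 50, 6,
               dimnames = list(sprintf("s%02d", 1:50), sprintf("m%d", 1:6)))
  enc2 <- fit_encoder(G2, rownames(G2)[1:30])
  Xtr <- encode_genotypes(enc2, G2[1:30, ])
  expect_equal(unname(colMeans(Xtr)), rep(0, ncol(Xtr)))
  expect_equal(unname(apply(Xtr, 2, sd)), rep(1, ncol(Xtr)))
})

test_that("the CNN solves a linearly separable toy within 50 epochs", {
  b <- separable_bundle()
  sp <- split_dataset(b$phenotypes, seed = 11)
  st <- setNames(b$phenotypes$status, b$phenotypes$sample_id)
  enc <- fit_encoder(b$genotypes * 1.0, sp$train)
  x_tr <- encode_genotypes(enc, b$genotypes[sp$train, ] * 1.0)
  x_va <- encode_genotypes(enc, b$genotypes[sp$val, ] * 1.0)
  fit <- train_classifier(x_tr, st[sp$train], x_va, st[sp$val],
                          cnn_spec(max_epochs = 50, seed = 3))
  expect_equal(max(fit$log$val_acc), 1.0)
})

test_that("nothing is learnable from permuted labels", {
  b <- separable_bundle(n = 800, noise_snps = 10, seed = 12)
  set.seed(13)
  ph <- b$phenotypes
  ph$status <- sample(ph$status)     # break the genotype-phenotype link
  sp <- split_dataset(ph, seed = 14)
  st <- setNames(ph$status, ph$sample_id)
  enc <- fit_encoder(b$genotypes * 1.0, sp$train)
  x_tr <- encode_genotypes(enc, b$genotypes[sp$train, ] * 1.0)
  x_va <- encode_genotypes(enc, b$genotypes[sp$val, ] * 1.0)
  x_te <- encode_genotypes(enc, b$genotypes[sp$test, ] * 1.0)
  fit <- train_classifier(x_tr, st[sp$train], x_va, st[sp$val],
                          cnn_spec(max_epochs = 60, seed = 15))
  auc <- auc_rank(predict(fit, x_te), st[sp$test])
  expect_gte(auc, 0.4)
  expect_lte(auc, 0.6)
})

test_that("training is deterministic given seed and adapts to short inputs", {
  b <- separable_bundle(n = 120, noise_snps = 2, seed = 16)
  sp <- split_dataset(b$phenotypes, seed = 17)
  st <- setNames(b$phenotypes$status, b$phenotypes$sample_id)
  enc <- fit_encoder(b$genotypes * 1.0, sp$train)
  x_tr <- encode_genotypes(enc, b$genotypes[sp$train, ] * 1.0)
  x_va <- encode_genotypes(enc, b$genotypes[sp$val, ] * 1.0)
  spec <- cnn_spec(max_epochs = 15, seed = 5)
  f1 <- train_classifier(x_tr, st[sp$train], x_va, st[sp$val], spec)
  f2 <- train_classifier(x_tr, st[sp$train], x_va, st[sp$val], spec)
  expect_equal(f1$model$layers, f2$model$layers)
  expect_identical(f1$log, f2$log)

  # input shorter than the kernel: effective kernel shrinks, still trains
  x1 <- x_tr[, 1, drop = FALSE]
  xv1 <- x_va[, 1, drop = FALSE]
  f3 <- train_classifier(x1, st[sp$train], xv1, st[sp$val],
                         cnn_spec(max_epochs = 10, seed = 6))
  expect_s3_class(f3, "cnn_fit")
  expect_length(predict(f3, xv1), nrow(xv1))
})

test_that("metrics identities hold on fixed and random confusion matrices", {
  scores <- c(rep(0.9, 90), rep(0.1, 10), rep(0.1, 95), rep(0.9, 5))
  labels <- rep(c(1, 0), c(100, 100))
  m <- classification_metrics(scores, labels)
  expect_equal(m$se, 0.90)
  expect_equal(m$sp, 0.95)
  expect_equal(m$acc, 0.925)
  expect_equal(m$or_, 171.0)
  expect_false(m$or_corrected)

  set.seed(8)
  for (i in 1:20) {
    n <- 50
    s <- runif(n); l <- rbinom(n, 1, 0.4)
    if (length(unique(l)) < 2) next
    mm <- classification_metrics(s, l, threshold = 0.5)
    cf <- mm$confusion
    expect_equal(mm$acc, (cf["TP"] + cf["TN"]) / n, ignore_attr = TRUE)
    expect_equal(mm$se, cf["TP"] / (cf["TP"] + cf["FN"]), ignore_attr = TRUE)
    expect_equal(mm$sp, cf["TN"] / (cf["TN"] + cf["FP"]), ignore_attr = TRUE)
  }

  # zero cell triggers the +0.5 continuity correction and the flag
  mz <- classification_metrics(c(0.9, 0.9, 0.1), c(1, 1, 0))
  expect_true(mz$or_corrected)
  expect_equal(mz$or_, (2.5 * 1.5) / (0.5 * 0.5))
})

test_that("AUC follows the rank convention and matches an independent oracle", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_rank(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(auc_rank(c(0.1, 0.9), c(1, 1)), "single-class")

  skip_if_not_installed("pROC")
  set.seed(9)
  s <- runif(80); l <- rbinom(80, 1, 0.5)
  expect_equal(auc_rank(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE))),
               tolerance = 1e-12)
  # invariance under strictly increasing transforms
  expect_equal(auc_rank(qlogis(pmin(pmax(s, 1e-6), 1 - 1e-6)), l),
               auc_rank(s, l))
})

test_that("model selection prefers accuracy, breaks ties toward fewer SNPs", {
  b <- separable_bundle(n = 240, noise_snps = 6, seed = 18)
  sp <- split_dataset(b$phenotypes, seed = 19)
  subsets <- structure(list(
    `5e-02` = colnames(b$genotypes),          # signal + all noise
    `5e-03` = "sig",                          # signal only
    `5e-08` = character(0)),
    class = c("threshold_subsets", "list"))
  sel <- suppressWarnings(
    select_best_model(b$genotypes * 1.0, b$phenotypes, subsets, sp,
                      cnn_spec(max_epochs = 40, seed = 20)))
  # both non-empty subsets contain the separating SNP -> both reach
  # validation accuracy 1; the tie must go to the 1-SNP model
  accs <- sel$val_metrics_by_tau$val_acc
  expect_equal(max(accs), 1.0)
  if (sum(accs == 1) > 1) expect_identical(sel$best_tau, "5e-03")
  expect_equal(sel$test_metrics$acc, 1.0)
  # test metrics exist only for the winner; per-tau table carries none
  expect_false(any(grepl("test", names(sel$val_metrics_by_tau))))
  expect_error(select_best_model(
    b$genotypes * 1.0, b$phenotypes,
    structure(list(`5e-02` = character(0)),
              class = c("threshold_subsets", "list")),
    sp, cnn_spec()), "empty")
})
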