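#' Rank SNPs by contribution score
#'
#' Descending contribution; ties broken by ascending association p-value
#' (when present), then lexicographic SNP id. Stable, deterministic and
#' invariant under input row permutation.
#'
#' @param contributions A contribution table with columns `snp_id`,
#'   `contribution` and optionally `assoc_p`.
#' @return The table reordered with a `rank` column (1 = highest score).
#' @export
rank_snps <- function(contributions) {
  stopifnot(nrow(contributions) >= 1,
            all(c("snp_id", "contribution") %in% names(contributions)))
  pv <- if ("assoc_p" %in% names(contributions)) contributions$assoc_p
        else rep(NA_real_, nrow(contributions))
  pv_key <- ifelse(is.na(pv), Inf, pv)
  ord <- order(-contributions$contribution, pv_key, contributions$snp_id)
  out <- contributions[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("contribution_table", "data.frame")
  out
}

#' Re-evaluate prediction with top-k SNP subsets
#'
#' For each `k`, retrains the classifier from scratch on only the top-k
#' ranked SNPs using the same splits and seed, and evaluates it on the test
#' split. An input-masking mode (top-k inputs kept, all others fixed at the
#' background/mean encoding of zero) is available for comparison with the
#' retraining default.
#'
#' @param genotypes Complete (imputed) dosage matrix.
#' @param phenotypes Phenotype table.
#' @param ranked A [rank_snps()] table.
#' @param splits A [split_dataset()] result.
#' @param spec A [cnn_spec()].
#' @param k_list Integer vector of subset sizes (default `c(3, 20)`).
#' @param mode `"retrain"` (default) or `"mask"`; masking requires `fit`
#'   and `encoder` of the full model.
#' @param fit,encoder Full-model fit/encoder, only for `mode = "mask"`.
#' @param threshold Decision threshold.
#' @param variants Optional variant table to restore genomic SNP order.
#' @return A `data.frame` (class `topk_report`): one row per k with test
#'   metrics; retained SNP ids attached as attribute `snp_ids`.
#' @export
topk_evaluation <- function(genotypes, phenotypes, ranked, splits, spec,
                            k_list = c(3L, 20L), mode = c("retrain", "mask"),
                            fit = NULL, encoder = NULL, threshold = 0.5,
                            variants = NULL) {
  mode <- match.arg(mode)
  m <- nrow(ranked)
  if (any(k_list > m))
    stop_config("topk_evaluation: k exceeds the number of ranked SNPs (",
                m, ")")
  status <- stats::setNames(phenotypes$status, phenotypes$sample_id)
  rows <- list(); kept <- list()
  for (k in sort(as.integer(k_list))) {
    ids <- ranked$snp_id[seq_len(k)]
    if (!is.null(variants)) {           # genomic order for the conv axis
      vo <- variants[variants$snp_id %in% ids, ]
      ids <- vo$snp_id[order(vo$chrom, vo$pos)]
    }
    kept[[as.character(k)]] <- ids
    if (mode == "retrain") {
      enc <- fit_encoder(genotypes[, ids, drop = FALSE], splits$train)
      x_tr <- encode_genotypes(enc, genotypes[splits$train, , drop = FALSE])
      x_va <- encode_genotypes(enc, genotypes[splits$val, , drop = FALSE])
      fit_k <- train_classifier(x_tr, status[splits$train],
                                x_va, status[splits$val], spec)
      x_te <- encode_genotypes(enc, genotypes[splits$test, , drop = FALSE])
      scores <- predict(fit_k, x_te)
    } else {
      stopifnot(!is.null(fit), !is.null(encoder))
      x_te <- encode_genotypes(encoder, genotypes[splits$test, , drop = FALSE])
      x_te[, setdiff(colnames(x_te), ids)] <- 0  # mean encoding
      scores <- predict(fit, x_te)
    }
    tm <- classification_metrics(scores, status[splits$test], threshold,
                                 split = "test")
    rows[[as.character(k)]] <- data.frame(
      k = k, se = tm$se, sp = tm$sp, acc = tm$acc, auc = tm$auc,
      or_ = tm$or_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "snp_ids") <- kept
  attr(out, "mode") <- mode
  class(out) <- c("topk_report", "data.frame")
  out
}

#' Recovery of planted causal SNPs (simulation only)
#'
#' @param ranked A [rank_snps()] table.
#' @param variants Variant table carrying `is_causal` flags.
#' @param k_list k values for precision-at-k.
#' @return List of class `recovery_report`: `precision_at` (named vector),
#'   `causal_ranks` (named), `median_causal_rank`.
#' @export
recovery_metrics <- function(ranked, variants, k_list = c(3L, 20L)) {
  if (is.null(variants$is_causal) || all(is.na(variants$is_causal)))
    stop("recovery_metrics: variants carry no is_causal flags; ",
         "this operation applies to simulated data only")
  causal <- variants$snp_id[variants$is_causal %in% TRUE]
  prec <- vapply(k_list, function(k) {
    topk <- ranked$snp_id[seq_len(min(k, nrow(ranked)))]
    length(intersect(topk, causal)) / k
  }, numeric(1))
  names(prec) <- paste0("k", k_list)
  cr <- stats::setNames(match(causal, ranked$snp_id), causal)
  structure(list(precision_at = prec, causal_ranks = cr,
                 median_causal_rank = stats::median(cr, na.rm = TRUE)),
            class = "recovery_report")
}

#' Summarize genomic location categories of ranked SNPs
#'
#' Counts annotation labels over the categories Missense, Intron, UTR-3,
#' Upstream, Downstream; anything else is counted under `other` with a
#' warning. "Within genes" is Missense + Intron + UTR-3.
#'
#' @param ranked A table with an `annotation` (or `located`) column.
#' @return List: `counts` (named vector), `within_genes`.
#' @export
annotate_summary <- function(ranked) {
  lab <- ranked$annotation %||% ranked$located
  if (is.null(lab)) stop_config("annotate_summary: no annotation column")
  lab <- lab[!is.na(lab)]
  known <- c("Missense", "Intron", "UTR-3", "Upstream", "Downstream")
  counts <- vapply(known, function(k) sum(lab == k), numeric(1))
  other <- length(lab) - sum(counts)
  if (other > 0)
    warning(other, " label(s) outside the known categories counted as 'other'",
            call. = FALSE)
  counts <- c(counts, other = other)
  list(counts = counts,
       within_genes = unname(counts["Missense"] + counts["Intron"] +
                               counts["UTR-3"]))
}

#' Default pipeline configuration
#'
#' Nested configuration driving [run_pipeline()]; every block mirrors one
#' stage (`simulate`, `qc`, `assoc`, `model`, `prioritize`). Values may
#' also be loaded from a YAML file with [read_pipeline_config()].
#'
#' @param seed Master seed (mandatory); stage seeds derive from it.
#' @param n_subjects,m_snps,k_causal Simulation shortcuts (see [sim_config()]).
#' @param ... Overrides merged into the `simulate` block.
#' @return Nested list of class `pipeline_config`.
#' @export
default_config <- function(seed, n_subjects = 2000L, m_snps = 1000L,
                           k_causal = 10L, ...) {
  structure(list(
    seed = as.integer(seed),
    simulate = utils::modifyList(
      list(n_subjects = n_subjects, m_snps = m_snps, k_causal = k_causal,
           case_fraction_target = 0.176, maf_range = c(0.2, 0.4),
           causal_log_or_range = c(log(2), log(3)), n_subpops = 2L,
           fst = 0.05, missing_rate = 0.02),
      list(...)),
    qc = list(snp_call_rate_min = 0.95, sample_call_rate_min = 0.95,
              maf_min = 0.01, hwe_p_min = 1e-6),
    assoc = list(k_pcs = 2L,
                 thresholds = c(5e-2, 5e-3, 5e-4, 5e-5, 5e-6, 5e-7, 5e-8)),
    model = list(),          # cnn_spec() overrides
    prioritize = list(k_list = c(3L, 20L), background_size = 100L,
                      decision_threshold = 0.5)
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' The file must carry a top-level `seed`; recognized blocks are
#' `simulate`, `qc`, `assoc`, `model`, `prioritize` and (alternatively to
#' `simulate`) `input` with `vcf`/`ped_prefix` and `phenotypes` paths.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) stop_config("config: top-level `seed` is mandatory")
  cfg <- default_config(raw$seed)
  for (blk in c("simulate", "qc", "assoc", "model", "prioritize"))
    if (!is.null(raw[[blk]]))
      cfg[[blk]] <- utils::modifyList(cfg[[blk]], raw[[blk]])
  if (!is.null(raw$input)) { cfg$input <- raw$input; cfg$simulate <- NULL }
  if (is.null(raw$simulate) && is.null(raw$input) &&
      !isTRUE(raw$use_default_simulation))
    stop_config("config: needs a `simulate:` block or an `input:` block")
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> QC -> imputation -> PCs -> association
#' scan -> threshold subsets -> split -> per-threshold CNN training and
#' model selection -> Deep SHAP attribution -> contribution ranking ->
#' top-k re-evaluation (-> causal-recovery metrics when the data are
#' simulated), in that order. Every stage is deterministic given the
#' config; when `out_dir` is given, all artifacts are written there
#' (config.yaml, qc.json, assoc.tsv, metrics_by_threshold.tsv,
#' contributions.tsv, topk.tsv, recovery.json, metrics_test.json).
#'
#' @param config A `pipeline_config` (see [default_config()]), or the path
#'   of a YAML file for [read_pipeline_config()].
#' @param out_dir Optional run directory.
#' @return List of class `pipeline_result` with elements `qc_report`,
#'   `assoc`, `subsets`, `selection`, `attributions`, `contributions`,
#'   `topk`, `recovery` (NULL for real data), `splits`, `bundle`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "setup"
  on.exit(if (!is.null(stage))
    message("run_pipeline: failed during stage '", stage, "'"), add = TRUE)

  # -- data ---------------------------------------------------------------
  stage <- "simulate/load"
  simulated <- !is.null(config$simulate)
  if (simulated) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% config$seed
    scfg <- do.call(sim_config, sim_args)
    bundle <- simulate_dataset(scfg)
  } else if (!is.null(config$input)) {
    inp <- config$input
    bundle <- if (!is.null(inp$vcf)) read_vcf(inp$vcf)
              else if (!is.null(inp$ped_prefix)) read_ped_map(inp$ped_prefix)
              else stop_config("input block needs `vcf` or `ped_prefix`")
    if (!is.null(inp$phenotypes)) {
      ph <- read_phenotype_tsv(inp$phenotypes)
      ph <- ph[match(rownames(bundle$genotypes), ph$sample_id), ]
      rownames(ph) <- NULL
      if (anyNA(ph$sample_id))
        stop_config("phenotype file does not cover all genotyped samples")
      bundle <- dataset_bundle(bundle$genotypes, bundle$variants, ph)
    }
    if (is.null(bundle$phenotypes))
      stop_config("pipeline needs phenotypes (status) for every sample")
  } else stop_config("config provides neither `simulate` nor `input`")

  # -- qc ------------------------------------------------------------------
  stage <- "qc"
  qc_res <- apply_qc(bundle, do.call(qc_config, config$qc))
  bundle <- qc_res$bundle
  stage <- "impute"
  G <- impute_missing(bundle$genotypes)

  # -- association scan ----------------------------------------------------
  stage <- "pca"
  pcs <- compute_pcs(G, k = config$assoc$k_pcs)
  stage <- "assoc"
  covs <- covariate_table(bundle$phenotypes, pcs)
  assoc <- logistic_scan(G, bundle$phenotypes, covs,
                         variants = bundle$variants)
  subsets <- select_snp_subsets(assoc, thresholds = config$assoc$thresholds)

  # -- classifier ----------------------------------------------------------
  stage <- "split"
  splits <- split_dataset(bundle$phenotypes, seed = config$seed)
  stage <- "train/select"
  spec_args <- utils::modifyList(list(seed = config$seed), config$model)
  spec <- do.call(cnn_spec, spec_args)
  thr <- config$prioritize$decision_threshold
  sel <- select_best_model(G, bundle$phenotypes, subsets, splits, spec,
                           threshold = thr)

  # -- attribution + ranking ----------------------------------------------
  stage <- "attribute"
  status <- stats::setNames(bundle$phenotypes$status,
                            bundle$phenotypes$sample_id)
  x_tr <- encode_genotypes(sel$encoder, G[splits$train, , drop = FALSE])
  bg <- sample_background(x_tr, config$prioritize$background_size,
                          seed = config$seed)
  x_te <- encode_genotypes(sel$encoder, G[splits$test, , drop = FALSE])
  attributions <- NULL; contributions <- NULL; topk <- NULL; recovery <- NULL
  attrib_ok <- TRUE
  attributions <- compute_attributions(sel$fit, x_te, bg)
  pvec <- stats::setNames(assoc$p, assoc$snp_id)
  contributions <- tryCatch(
    contribution_scores(attributions, sel$test_scores, status[splits$test],
                        threshold = thr, assoc_p = pvec),
    error = function(e) {
      warning("attribution aggregation skipped: ", conditionMessage(e),
              call. = FALSE)
      attrib_ok <<- FALSE
      NULL
    })

  # -- top-k + recovery ----------------------------------------------------
  if (attrib_ok) {
    stage <- "topk"
    k_list <- unique(pmin(config$prioritize$k_list, nrow(contributions)))
    if (length(k_list))
      topk <- topk_evaluation(G, bundle$phenotypes, contributions, splits,
                              spec, k_list = k_list, threshold = thr,
                              variants = bundle$variants)
    if (simulated && any(bundle$variants$is_causal %in% TRUE)) {
      stage <- "recovery"
      recovery <- recovery_metrics(contributions, bundle$variants,
                                   k_list = config$prioritize$k_list)
    }
  }

  stage <- "write"
  result <- structure(list(
    qc_report = qc_res$report, assoc = assoc, subsets = subsets,
    selection = sel, attributions = attributions,
    contributions = contributions, topk = topk, recovery = recovery,
    splits = splits, bundle = bundle, config = config),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  stage <- NULL
  result
}

# Write the fixed run-directory layout.
write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(result$config), file.path(out_dir, "config.yaml"))
  write_qc_report_json(result$qc_report, file.path(out_dir, "qc.json"))
  write_tsv(result$assoc, file.path(out_dir, "assoc.tsv"))
  write_tsv(result$selection$val_metrics_by_tau,
            file.path(out_dir, "metrics_by_threshold.tsv"))
  write_metrics_json(result$selection$test_metrics,
                     file.path(out_dir, "metrics_test.json"))
  if (!is.null(result$contributions))
    write_tsv(result$contributions, file.path(out_dir, "contributions.tsv"))
  if (!is.null(result$topk))
    write_tsv(result$topk, file.path(out_dir, "topk.tsv"))
  if (!is.null(result$recovery))
    jsonlite::write_json(
      list(precision_at = as.list(result$recovery$precision_at),
           causal_ranks = as.list(result$recovery$causal_ranks),
           median_causal_rank = result$recovery$median_causal_rank),
      file.path(out_dir, "recovery.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Load the bundled top-SNP worked-example table
#'
#' A packaged fixture transcribing a published table of 20 top-ranked SNPs
#' (chromosome, position, id, location category, nearest genes, association
#' p-value and mean |SHAP| contribution score), used in worked examples and
#' tests of [rank_snps()] and [annotate_summary()].
#'
#' @return A data.frame with columns `chrom`, `pos`, `snp_id`, `located`,
#'   `nearest_genes`, `p`, `shap`.
#' @export
load_top_snp_table <- function() {
  path <- system.file("extdata", "table2.tsv", package = "gwasxplain",
                      mustWork = TRUE)
  read_tsv(path)
}
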