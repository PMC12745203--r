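#' Bundle genotypes, variants and phenotypes into one dataset object
#'
#' Checks mutual consistency of the three tables (matching sample ids,
#' matching variant ids, no duplicates) and returns them as one list.
#'
#' @param genotypes Numeric matrix, subjects x SNPs, entries in {0,1,2,NA}
#'   (non-integer dosages are allowed after imputation).
#' @param variants Variant table (see [sample_variants()] for the schema).
#' @param phenotypes Phenotype table, or `NULL` for genotype-only bundles.
#' @return A list of class `dataset_bundle`.
#' @export
dataset_bundle <- function(genotypes, variants, phenotypes = NULL) {
  if (is.null(rownames(genotypes)) || is.null(colnames(genotypes)))
    stop_config("genotypes must carry sample_ids (rownames) and snp_ids (colnames)")
  if (anyDuplicated(rownames(genotypes)))
    stop_config("duplicate sample ids in genotype matrix")
  if (anyDuplicated(colnames(genotypes)))
    stop_config("duplicate snp ids in genotype matrix")
  if (!identical(colnames(genotypes), variants$snp_id))
    stop_config("variant table and genotype columns are inconsistent")
  ok <- is.na(genotypes) | (genotypes >= 0 & genotypes <= 2)
  if (!all(ok))
    stop_config("genotype entries must lie in [0,2] or be missing")
  if (!is.null(phenotypes)) {
    if (!identical(phenotypes$sample_id, rownames(genotypes)))
      stop_config("phenotype sample ids do not match genotype rows")
  }
  structure(list(genotypes = genotypes, variants = variants,
                 phenotypes = phenotypes),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf("<dataset_bundle> %d subjects x %d SNPs; phenotypes: %s\n",
              nrow(x$genotypes), ncol(x$genotypes),
              if (is.null(x$phenotypes)) "absent" else "present"))
  invisible(x)
}

#' Write a dataset bundle as VCF v4.2
#'
#' Emits a minimal GT-only VCF: `##fileformat=VCFv4.2`, one contig header
#' per chromosome, one sample column per subject. Genotype 0 is written as
#' `0/0`, 1 as `0/1`, 2 as `1/1`, missing as `./.`. Positions are 1-based.
#' Round-trips exactly through [read_vcf()]. Imputed (non-integer) dosages
#' cannot be represented in GT and are rejected.
#'
#' @param bundle A [dataset_bundle()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(bundle, path) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  G <- bundle$genotypes
  v <- bundle$variants
  if (any(!is.na(G) & G != round(G)))
    stop_config("write_vcf: non-integer dosages cannot be encoded as GT")
  con <- file(path, "wb")  # "wb" keeps \n line ends on every platform
  on.exit(close(con))
  wl <- function(x) writeLines(x, con, sep = "\n")
  wl("##fileformat=VCFv4.2")
  wl(sprintf("##contig=<ID=%s>", unique(v$chrom)))
  wl('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  wl(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
             "INFO", "FORMAT", rownames(G)), collapse = "\t"))
  codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(nrow(v))) {
    g <- G[, j]
    gt <- ifelse(is.na(g), "./.", codes[as.character(g)])
    wl(paste(c(v$chrom[j], v$pos[j], v$snp_id[j], v$ref_allele[j],
               v$alt_allele[j], ".", ".", ".", "GT", gt), collapse = "\t"))
  }
  invisible(path)
}

#' Read a GT-only biallelic VCF into a dataset bundle (no phenotypes)
#'
#' Parsing is delegated to \pkg{vcfR}; the result is validated strictly:
#' multiallelic records and records without a GT field are rejected with an
#' error naming the offending record, and unknown GT tokens raise rather
#' than being coerced. Both `/` and `|` genotype separators are accepted;
#' dosage counts the ALT allele as written (no minor-allele re-orientation).
#'
#' @param path VCF file path.
#' @return A [dataset_bundle()] with `phenotypes = NULL`.
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  bad <- grepl(",", alt, fixed = TRUE)
  if (any(bad))
    stop_format("read_vcf: multiallelic record not supported: ",
                paste(fix[bad, "ID"], collapse = ", "),
                " (record ", paste(which(bad), collapse = ", "), ")")
  gt_raw <- vcf@gt
  if (is.null(gt_raw) || !"FORMAT" %in% colnames(gt_raw))
    stop_format("read_vcf: no genotype (FORMAT) columns present")
  fmt <- gt_raw[, "FORMAT"]
  no_gt <- !vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) "GT" %in% f, logical(1))
  if (any(no_gt))
    stop_format("read_vcf: record without GT field: ",
                paste(fix[no_gt, "ID"], collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  map <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2,
           "0|0" = 0, "0|1" = 1, "1|0" = 1, "1|1" = 2)
  vals <- map[gt]
  unknown <- !is.na(gt) & is.na(vals) & gt != "./." & gt != ".|."
  if (any(unknown)) {
    w <- which(unknown, arr.ind = TRUE)[1, ]
    stop_format("read_vcf: unrecognized GT token '", gt[unknown][1],
                "' at record ", rownames(gt)[w[1]] %||% w[1],
                ", sample ", colnames(gt)[w[2]])
  }
  G <- matrix(as.integer(vals), nrow = ncol(gt), ncol = nrow(gt),
              byrow = TRUE,
              dimnames = list(colnames(gt), fix[, "ID"]))
  variants <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    snp_id = fix[, "ID"],
    ref_allele = fix[, "REF"],
    alt_allele = alt,
    ancestral_maf = NA_real_,
    is_causal = NA,
    beta_true = NA_real_,
    annotation = NA_character_,
    stringsAsFactors = FALSE
  )
  class(variants) <- c("variant_table", "data.frame")
  dataset_bundle(G, variants, NULL)
}

#' Write a dataset bundle as PLINK text (.ped/.map)
#'
#' `.map` columns: chrom, snp_id, genetic distance (0), position. `.ped`
#' columns: FID IID PAT MAT SEX PHENO then two allele columns per SNP
#' (dosage 0 -> ref/ref, 1 -> ref/alt, 2 -> alt/alt, missing -> `0 0`).
#' PHENO uses PLINK's 1=control / 2=case coding (0 when unknown).
#'
#' @param bundle A [dataset_bundle()].
#' @param prefix Output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return `prefix`, invisibly.
#' @export
write_ped_map <- function(bundle, prefix) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  G <- bundle$genotypes
  v <- bundle$variants
  if (any(!is.na(G) & G != round(G)))
    stop_config("write_ped_map: non-integer dosages cannot be encoded")
  utils::write.table(
    data.frame(v$chrom, v$snp_id, 0L, v$pos),
    paste0(prefix, ".map"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE, eol = "\n")
  n <- nrow(G); m <- ncol(G)
  a1 <- matrix("0", n, m); a2 <- matrix("0", n, m)
  for (j in seq_len(m)) {
    g <- G[, j]
    a1[, j] <- ifelse(is.na(g), "0", ifelse(g >= 1, v$alt_allele[j], v$ref_allele[j]))
    a2[, j] <- ifelse(is.na(g), "0", ifelse(g == 2, v$alt_allele[j], v$ref_allele[j]))
  }
  pheno <- if (is.null(bundle$phenotypes)) rep(0L, n) else
    bundle$phenotypes$status + 1L
  sex <- if (is.null(bundle$phenotypes)) rep(0L, n) else
    # PLINK sex coding: 1=male, 2=female, 0=unknown; our 0/1 sex keeps 1 as male
    ifelse(bundle$phenotypes$sex == 1, 1L, 2L)
  alleles <- matrix("", n, 2L * m)
  alleles[, seq(1L, 2L * m, by = 2L)] <- a1
  alleles[, seq(2L, 2L * m, by = 2L)] <- a2
  ped <- cbind(rownames(G), rownames(G), "0", "0", sex, pheno, alleles)
  utils::write.table(ped, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(prefix)
}

#' Read PLINK text (.ped/.map) into a dataset bundle
#'
#' Alleles at each SNP are oriented against the `.map`-order allele pair
#' observed in the data; the ALT allele is taken from the writer's
#' convention when recoverable (two observed alleles), otherwise the single
#' observed allele is treated as REF. Dosage counts the ALT allele.
#'
#' @param prefix Path prefix of the `.ped`/`.map` pair.
#' @param alt_alleles Optional character vector of ALT alleles per SNP (in
#'   `.map` order) fixing orientation explicitly, e.g. from a variant table.
#' @return A [dataset_bundle()]; phenotypes are populated from the PED
#'   PHENO column when it uses the 1/2 coding.
#' @export
read_ped_map <- function(prefix, alt_alleles = NULL) {
  map <- utils::read.table(paste0(prefix, ".map"), sep = "\t",
                           col.names = c("chrom", "snp_id", "cm", "pos"),
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  ped <- utils::read.table(paste0(prefix, ".ped"), sep = "",
                           colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6L + 2L * m)
    stop_format("read_ped_map: .ped has ", ncol(ped),
                " columns, expected ", 6L + 2L * m)
  n <- nrow(ped)
  ids <- ped[[2]]
  G <- matrix(NA_integer_, n, m, dimnames = list(ids, map$snp_id))
  ref <- character(m); altv <- character(m)
  for (j in seq_len(m)) {
    A1 <- ped[[6L + 2L * j - 1L]]
    A2 <- ped[[6L + 2L * j]]
    obs <- setdiff(unique(c(A1, A2)), "0")
    if (length(obs) > 2L)
      stop_format("read_ped_map: >2 alleles at ", map$snp_id[j])
    if (!is.null(alt_alleles)) {
      alt <- alt_alleles[j]
      rf <- setdiff(obs, alt)[1]
      if (is.na(rf)) rf <- "N"
    } else if (length(obs) == 2L) {
      # minor allele (by count) as ALT; ties broken lexicographically
      cnt <- table(factor(c(A1, A2), levels = obs))
      obs <- obs[order(cnt, obs)]
      alt <- obs[1]; rf <- obs[2]
    } else {
      rf <- if (length(obs)) obs[1] else "N"
      alt <- "N"
    }
    ref[j] <- rf; altv[j] <- alt
    miss <- A1 == "0" | A2 == "0"
    G[, j] <- ifelse(miss, NA_integer_, (A1 == alt) + (A2 == alt))
  }
  variants <- data.frame(
    chrom = map$chrom, pos = map$pos, snp_id = map$snp_id,
    ref_allele = ref, alt_allele = altv,
    ancestral_maf = NA_real_, is_causal = NA, beta_true = NA_real_,
    annotation = NA_character_, stringsAsFactors = FALSE)
  class(variants) <- c("variant_table", "data.frame")
  phen <- NULL
  ph <- suppressWarnings(as.integer(ped[[6]]))
  if (all(!is.na(ph)) && all(ph %in% c(1L, 2L))) {
    phen <- data.frame(sample_id = ids, status = ph - 1L,
                       age = NA_real_,
                       sex = ifelse(as.integer(ped[[5]]) == 1L, 1L, 0L),
                       subpop = 1L, stringsAsFactors = FALSE)
    class(phen) <- c("phenotype_table", "data.frame")
  }
  dataset_bundle(G, variants, phen)
}

#' Read a phenotype/covariate TSV
#'
#' Requires a header with at least `sample_id`, `status`, `age`, `sex`.
#' `status` accepts {0, 1, case, control}; anything else raises.
#'
#' @param path TSV path.
#' @return A `phenotype_table` data.frame.
#' @export
read_phenotype_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "status", "age", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_format("phenotype file lacks required column(s): ",
                paste(miss, collapse = ", "))
  st <- tolower(df$status)
  status <- ifelse(st %in% c("1", "case"), 1L,
                   ifelse(st %in% c("0", "control"), 0L, NA_integer_))
  if (anyNA(status))
    stop_format("unknown status token(s): ",
                paste(unique(df$status[is.na(status)]), collapse = ", "))
  out <- data.frame(
    sample_id = df$sample_id,
    status = status,
    age = as.numeric(df$age),
    sex = as.integer(df$sex),
    subpop = if ("subpop" %in% names(df)) as.integer(df$subpop) else 1L,
    stringsAsFactors = FALSE)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Write a table as TSV with a stable column order
#'
#' @param df A data.frame (phenotypes, association results,
#'   contribution tables, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Serialize a metrics report as JSON
#'
#' Keys follow the fixed schema `se, sp, acc, auc, or_, confusion`.
#'
#' @param metrics A metrics report (see [classification_metrics()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(
    list(se = metrics$se, sp = metrics$sp, acc = metrics$acc,
         auc = metrics$auc, or_ = metrics$or_,
         confusion = as.list(metrics$confusion),
         split = metrics$split %||% NA),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
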