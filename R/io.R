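#' @useDynLib methgout, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats as.formula coef complete.cases cor lm model.matrix
#'   p.adjust pchisq plogis pnorm pt qlogis quantile rbinom rgamma rnorm
#'   runif sd setNames uniroot var vcov wilcox.test glm binomial rexp
#' @importFrom utils read.delim write.table head modifyList
"_PACKAGE"

# Internal conventions
#  - beta matrices and genotype matrices are plain numeric matrices with
#    samples in rows and probes/variants in columns (limma-style, transposed);
#    all joins between tables are by sample id, never by row order.
#  - missing values are NA and analyses are complete-case per test.

PROMOTER_FEATURES <- c("TSS1500", "TSS200", "5UTR")
GENOMIC_FEATURES <- c(PROMOTER_FEATURES, "1stExon", "Body", "3UTR", "intergenic")
CANDIDATE_CATEGORIES <- c("il1b_production", "expressed_macrophage_il1b",
                          "gouty_inflammation")

#' Validate a methylation beta matrix
#'
#' Checks that a samples-by-probes matrix of methylation beta values is
#' well-formed: unique sample and probe identifiers, and every non-missing
#' value inside the unit interval.
#'
#' @param betas Numeric matrix, samples in rows (rownames = sample ids),
#'   probes in columns (colnames = CpG probe ids).
#' @return The validated matrix, invisibly.
#' @export
validate_beta_matrix <- function(betas) {
  if (!is.matrix(betas) || !is.numeric(betas))
    stop("beta matrix must be a numeric matrix")
  if (is.null(rownames(betas)) || is.null(colnames(betas)))
    stop("beta matrix must carry sample ids (rownames) and probe ids (colnames)")
  if (anyDuplicated(rownames(betas)))
    stop("duplicate sample id: ",
         rownames(betas)[duplicated(rownames(betas))][1L])
  if (anyDuplicated(colnames(betas)))
    stop("duplicate probe id: ",
         colnames(betas)[duplicated(colnames(betas))][1L])
  bad <- which(!is.na(betas) & (betas < 0 | betas > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "beta value %.6g outside [0,1] at probe %s, sample %s",
      betas[bad[1L, 1L], bad[1L, 2L]],
      colnames(betas)[bad[1L, 2L]], rownames(betas)[bad[1L, 1L]]))
  }
  invisible(betas)
}

#' Read a methylation beta matrix from a tab-separated file
#'
#' The file has a header row; one axis holds samples and the other probes.
#' With `orientation = "auto"` the axis is inferred from the first header
#' field (`probe_id` or `sample_id`).
#'
#' @param path Path to a tab-separated file.
#' @param orientation One of `"auto"`, `"probes_in_rows"`, `"samples_in_rows"`.
#' @return A validated samples-by-probes numeric matrix.
#' @export
read_beta_matrix <- function(path,
                             orientation = c("auto", "probes_in_rows",
                                             "samples_in_rows")) {
  orientation <- match.arg(orientation)
  tab <- read_id_matrix(path, what = "beta")
  if (orientation == "auto") {
    orientation <- if (tab$id_name == "sample_id") "samples_in_rows"
                   else "probes_in_rows"
  }
  m <- tab$values
  if (orientation == "probes_in_rows") m <- t(m)
  validate_beta_matrix(m)
  m
}

#' Write a methylation beta matrix
#'
#' Writes probes in rows (the common dialect for methylation arrays) with a
#' `probe_id` first column; values are rendered at fixed precision so that
#' write/read round-trips are stable.
#'
#' @param betas Samples-by-probes beta matrix.
#' @param path Output path.
#' @param digits Number of significant digits used for values.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(betas, path, digits = 6L) {
  validate_beta_matrix(betas)
  write_id_matrix(t(betas), path, id_name = "probe_id", digits = digits)
}

#' Validate a genotype dosage matrix
#'
#' @param dosages Numeric matrix, samples in rows, variants in columns, with
#'   additive dosages in \{0, 1, 2\} (NA allowed).
#' @return The validated matrix, invisibly.
#' @export
validate_genotype_matrix <- function(dosages) {
  if (!is.matrix(dosages) || !is.numeric(dosages))
    stop("genotype matrix must be a numeric matrix")
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    stop("genotype matrix must carry sample ids (rownames) and variant ids (colnames)")
  if (anyDuplicated(rownames(dosages)))
    stop("duplicate sample id: ",
         rownames(dosages)[duplicated(rownames(dosages))][1L])
  if (anyDuplicated(colnames(dosages)))
    stop("duplicate variant id: ",
         colnames(dosages)[duplicated(colnames(dosages))][1L])
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop(sprintf("dosage %s at variant %s, sample %s is not in {0,1,2}",
                 format(dosages[bad[1L], bad[2L]]),
                 colnames(dosages)[bad[2L]], rownames(dosages)[bad[1L]]))
  }
  invisible(dosages)
}

#' Read genotypes from a VCF or a tab-separated dosage table
#'
#' VCF records must be biallelic; genotypes are converted to additive
#' alternate-allele dosages (GT field; `./.` becomes NA). A dosage table is
#' the dialect written by [write_genotype_matrix()]: variants in rows,
#' `variant_id` first column.
#'
#' @param path Path to a `.vcf` (optionally gzipped) or tab-separated file.
#' @return A samples-by-variants dosage matrix.
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    read_genotypes_vcf(path)
  } else {
    tab <- read_id_matrix(path, what = "dosage")
    m <- if (tab$id_name == "sample_id") tab$values else t(tab$values)
    validate_genotype_matrix(m)
    m
  }
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    i <- which(multi)[1L]
    stop(sprintf("multiallelic record at %s:%s not supported",
                 fix[i, "CHROM"], fix[i, "POS"]))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  count_alt <- function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1L]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles != "0")
  }
  dos <- vapply(seq_len(ncol(gt)), function(j)
    vapply(gt[, j], count_alt, numeric(1), USE.NAMES = FALSE),
    numeric(nrow(gt)))
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = nrow(gt))
  dimnames(dos) <- list(ids, colnames(gt))
  m <- t(dos)
  validate_genotype_matrix(m)
  m
}

#' Write a genotype dosage matrix
#'
#' @param dosages Samples-by-variants dosage matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(dosages, path) {
  validate_genotype_matrix(dosages)
  write_id_matrix(t(dosages), path, id_name = "variant_id", digits = 1L)
}

#' Read a sample covariate/phenotype sheet
#'
#' Expects tab-separated columns `sample_id`, `sex`, `age`, `pack_years`,
#' `smoking_status`, `alcohol`, `gout`, `urate_group`, `bmi`, `hba1c`,
#' `total_cholesterol`, plus optional `prop_*` cell-proportion columns.
#'
#' @param path Path to a tab-separated file.
#' @return A validated data frame.
#' @export
read_sample_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, comment.char = "#")
  validate_sample_table(df)
  df
}

#' Validate a sample table
#'
#' @param samples Data frame as described in [read_sample_table()].
#' @return The data frame, invisibly.
#' @export
validate_sample_table <- function(samples) {
  required <- c("sample_id", "sex", "age", "pack_years", "smoking_status",
                "alcohol", "gout", "urate_group")
  miss <- setdiff(required, names(samples))
  if (length(miss) > 0)
    stop("sample table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample id: ",
         samples$sample_id[duplicated(samples$sample_id)][1L])
  if (!all(samples$gout %in% c(0, 1)))
    stop("gout flag must be 0/1")
  if (!all(samples$smoking_status %in% c("never", "former", "current")))
    stop("smoking_status must be never/former/current")
  if (!all(samples$urate_group %in% c("normouricemia", "hyperuricemia", "gout")))
    stop("urate_group must be normouricemia/hyperuricemia/gout")
  if (any(samples$urate_group == "gout" & samples$gout != 1))
    stop("urate_group 'gout' requires gout flag 1")
  if (any(samples$pack_years < 0, na.rm = TRUE))
    stop("pack_years must be non-negative")
  props <- grep("^prop_", names(samples), value = TRUE)
  if (length(props) > 0) {
    w <- as.matrix(samples[, props, drop = FALSE])
    if (any(w < -1e-8 | w > 1 + 1e-8, na.rm = TRUE))
      stop("cell proportions must lie in [0,1]")
    s <- rowSums(w)
    if (any(s > 1 + 1e-6, na.rm = TRUE))
      stop("cell proportions must sum to at most 1")
  }
  invisible(samples)
}

#' Read a CpG annotation manifest
#'
#' Tab-separated columns: `probe_id`, `chromosome`, `position` (1-based,
#' hg19 by convention), `gene`, `genomic_feature`, `cpg_island`.
#'
#' @param path Path to a tab-separated file.
#' @return A validated data frame.
#' @export
read_cpg_annotation <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, comment.char = "#",
                   colClasses = c(chromosome = "character"))
  validate_cpg_annotation(df)
  df
}

#' Validate a CpG annotation manifest
#'
#' @param annotation Data frame as described in [read_cpg_annotation()].
#' @return The data frame, invisibly.
#' @export
validate_cpg_annotation <- function(annotation) {
  required <- c("probe_id", "chromosome", "position", "gene", "genomic_feature")
  miss <- setdiff(required, names(annotation))
  if (length(miss) > 0)
    stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(annotation$probe_id))
    stop("duplicate probe id: ",
         annotation$probe_id[duplicated(annotation$probe_id)][1L])
  if (any(annotation$position < 1))
    stop("positions must be >= 1 (1-based coordinates)")
  bad <- setdiff(unique(annotation$genomic_feature), GENOMIC_FEATURES)
  if (length(bad) > 0)
    stop("unknown genomic_feature: ", paste(bad, collapse = ", "))
  invisible(annotation)
}

#' Read a variant annotation table
#'
#' Tab-separated columns: `variant_id`, `chromosome`, `position`, `ref`, `alt`.
#'
#' @param path Path to a tab-separated file.
#' @return A data frame.
#' @export
read_variant_annotation <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, comment.char = "#",
                   colClasses = c(chromosome = "character"))
  required <- c("variant_id", "chromosome", "position")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stop("variant annotation missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$variant_id))
    stop("duplicate variant id: ", df$variant_id[duplicated(df$variant_id)][1L])
  df
}

#' Write a results table
#'
#' Writes any record data frame produced by the pipeline as a tab-separated
#' file with a deterministic column order, a `# schema:` header comment, and
#' floating point values at fixed precision.
#'
#' @param records Data frame of records.
#' @param path Output path.
#' @param digits Significant digits for numeric columns.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path, digits = 10L) {
  stopifnot(is.data.frame(records))
  con <- file(path, open = "wt")
  on.exit(close(con))
  types <- vapply(records, function(x) class(x)[1L], character(1))
  writeLines(sprintf("# schema: %s",
                     paste(names(records), types, sep = ":", collapse = "\t")),
             con)
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), "NA",
                         sprintf(paste0("%.", digits, "g"), out[[j]]))
  }
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#'
#' Column classes are restored from the schema header.
#'
#' @param path Path to the file.
#' @return A data frame.
#' @export
read_results_table <- function(path) {
  first <- readLines(path, n = 1L)
  col_classes <- NA
  if (startsWith(first, "# schema:")) {
    schema <- strsplit(sub("^# schema: ", "", first), "\t")[[1L]]
    parts <- strsplit(schema, ":")
    col_classes <- vapply(parts, `[`, character(1), 2L)
    names(col_classes) <- vapply(parts, `[`, character(1), 1L)
    col_classes[!col_classes %in%
                  c("numeric", "integer", "character", "logical")] <- "character"
  }
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, comment.char = "#",
             check.names = FALSE, colClasses = col_classes)
}

# Shared reader for id-column matrices (beta / dosage dialects).
read_id_matrix <- function(path, what = "value") {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, comment.char = "#")
  id_name <- names(df)[1L]
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "NA")
      if (length(bad) > 0)
        stop(sprintf("non-numeric %s '%s' at row %s, column %s",
                     what, v[bad[1L]], ids[bad[1L]], names(vals)[j]))
      v <- num
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  list(id_name = id_name, values = m)
}

write_id_matrix <- function(m, path, id_name, digits = 6L) {
  df <- data.frame(id = rownames(m), stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df) <- id_name
  fmt <- paste0("%.", digits, "f")
  for (j in seq_len(ncol(m)))
    df[[colnames(m)[j]]] <- ifelse(is.na(m[, j]), "NA", sprintf(fmt, m[, j]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

# Nudge exact 0/1 betas into (0,1) for logit transforms only; stored data are
# never altered.
squeeze_beta <- function(b, eps = 1e-6) pmin(pmax(b, eps), 1 - eps)

logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)
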