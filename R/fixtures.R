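GOUT_CANDIDATES_MD5 <- "efa7bb8feae313e1b7e2c0fc8f17d6e3"

#' Load the curated gout candidate CpG table
#'
#' Nine promoter CpG sites mapped to genes regulating IL-1\eqn{\beta}
#' production or implicated in gouty inflammation, with their adjusted
#' case-minus-control methylation differences (percent), association
#' p-values, hg19 coordinates, and the outcome of the genetic/meQTL screen
#' (`meqtl_flag`: Y when no variant was concurrently associated with
#' methylation and gout) and of the causal inference test (`cit_flag`:
#' Y/N, or `not_applicable` when no shared variant existed).
#'
#' @return A 9-row data frame, one row per candidate CpG.
#' @export
load_gout_candidates <- function() {
  path <- system.file("extdata", "gout_candidate_cpgs.tsv",
                      package = "methgout", mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, GOUT_CANDIDATES_MD5))
    stop("candidate table fixture is corrupted (checksum mismatch: ", sum, ")")
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(chromosome = "character"))
  validate_candidate_table(df)
  df
}

#' Validate a candidate CpG table
#'
#' @param candidates Data frame in the dialect of [load_gout_candidates()].
#' @return The data frame, invisibly.
#' @export
validate_candidate_table <- function(candidates) {
  required <- c("probe_id", "delta_beta_percent", "p", "chromosome",
                "position", "gene", "genomic_feature", "meqtl_flag",
                "cit_flag", "category", "il1b_direction")
  miss <- setdiff(required, names(candidates))
  if (length(miss) > 0)
    stop("candidate table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(candidates$meqtl_flag %in% c("Y", "N")))
    stop("meqtl_flag must be Y or N")
  if (!all(candidates$cit_flag %in% c("Y", "N", "not_applicable")))
    stop("cit_flag must be Y, N or not_applicable")
  if (any(candidates$meqtl_flag == "Y" &
          candidates$cit_flag != "not_applicable"))
    stop("meqtl_flag Y requires cit_flag not_applicable")
  if (!all(candidates$category %in% CANDIDATE_CATEGORIES))
    stop("unknown candidate category")
  if (!all(candidates$il1b_direction %in% c("up", "down", "unknown")))
    stop("il1b_direction must be up, down or unknown")
  invisible(candidates)
}

#' Load reference methylation profiles for cell-type deconvolution
#'
#' By default loads the packaged synthetic blood reference (6 leukocyte
#' subsets x 300 discriminating probes; see the package vignette for how it
#' was constructed and what it does and does not emulate). A user-supplied
#' reference in the same dialect (tab-separated, `probe_id` first column,
#' one column per cell type) is accepted via `path`.
#'
#' @param path Optional path to a reference profile table.
#' @return A probes-by-cell-types numeric matrix with beta values in (0,1).
#' @export
load_reference_profiles <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "synthetic_blood_reference.tsv",
                        package = "methgout", mustWork = TRUE)
  tab <- read_id_matrix(path, what = "reference beta")
  R <- tab$values
  if (ncol(R) < 2) stop("reference must contain at least 2 cell types")
  if (any(R < 0 | R > 1, na.rm = TRUE))
    stop("reference beta values must lie in [0,1]")
  R
}

#' Load the curated IL-1\eqn{\beta} / gouty-inflammation gene list
#'
#' The literature-review step of the candidate filter, externalized as a
#' YAML resource mapping each gene to its category and its reported
#' direction of effect on IL-1\eqn{\beta} production.
#'
#' @param path Optional path to a YAML gene list in the packaged dialect.
#' @return A data frame with columns `gene`, `category`, `il1b_direction`.
#' @export
load_gene_list <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "il1b_gene_list.yaml",
                        package = "methgout", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  if (is.null(y$genes)) stop("gene list YAML must have a top-level 'genes' key")
  df <- do.call(rbind, lapply(y$genes, function(g)
    data.frame(gene = g$gene,
               category = g$category %||% "il1b_production",
               il1b_direction = g$il1b_direction %||% "unknown",
               stringsAsFactors = FALSE)))
  if (anyDuplicated(df$gene)) stop("duplicate gene in gene list")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
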