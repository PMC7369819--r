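# Orchestrates the full decision procedure:
#   deconvolution -> promoter EWAS -> candidate filter (FDR + curated gene
#   list) -> trait specificity -> three-group contrasts -> cis meQTL/disease
#   scans -> causal inference tests -> classification -> co-methylation of
#   survivors, and emits a classification report.

#' Classify one candidate CpG from its scans and causal inference tests
#'
#' Decision rule: a candidate with no variant concurrently associated with
#' its methylation and gout is `no_shared_variant` (the epigenetic
#' association has no common genetic driver; survives). A candidate whose
#' shared variants ALL pass the causal inference test (omnibus
#' p < `alpha_cit`) is `mediated` (methylation mediates the variant-gout
#' relationship; survives). Any unexplained shared variant leaves genetic
#' confounding on the table: `confounded` (dropped). Non-candidates are
#' `not_candidate`.
#'
#' @param ewas_row One row of [promoter_ewas()] output for the probe.
#' @param shared_variants Character vector of shared variant ids.
#' @param cit_results [cit_batch()] rows covering every shared variant.
#' @param candidate Is the probe a filtered candidate (FDR + gene list)?
#' @param alpha_cit Significance threshold for "mediated" (default 0.05).
#' @return One-row classification record.
#' @export
classify_cpg <- function(ewas_row, shared_variants, cit_results,
                         candidate = TRUE, alpha_cit = 0.05) {
  if (length(shared_variants) > 0) {
    miss <- setdiff(shared_variants, cit_results$variant_id)
    if (length(miss) > 0)
      stop("missing CIT result for shared variant(s): ",
           paste(miss, collapse = ", "))
  }
  status <- if (!candidate) {
    "not_candidate"
  } else if (length(shared_variants) == 0) {
    "no_shared_variant"
  } else {
    cr <- cit_results[cit_results$variant_id %in% shared_variants, ]
    if (all(cr$p_omnibus < alpha_cit)) "mediated" else "confounded"
  }
  data.frame(probe_id = ewas_row$probe_id,
             gene = ewas_row$gene %||% NA_character_,
             delta_beta_percent = 100 * ewas_row$delta_beta,
             p = ewas_row$p, q = ewas_row$q %||% NA_real_,
             candidate = candidate,
             n_shared = length(shared_variants),
             shared_variants = paste(shared_variants, collapse = ","),
             status = status,
             survives = status %in% c("no_shared_variant", "mediated"),
             stringsAsFactors = FALSE)
}

#' Classify a curated candidate table from its recorded flags
#'
#' Fixture mode: replays the classification logic directly on a candidate
#' table (dialect of [load_gout_candidates()]) whose `meqtl_flag` records
#' the genetic/meQTL screen outcome (Y = no shared variant) and whose
#' `cit_flag` records the causal inference test outcome.
#'
#' @param candidates Candidate table data frame.
#' @return Classification records, one per row, carrying `category` and
#'   `il1b_direction` through.
#' @export
classify_candidate_table <- function(candidates) {
  validate_candidate_table(candidates)
  status <- ifelse(candidates$meqtl_flag == "Y", "no_shared_variant",
                   ifelse(candidates$cit_flag == "Y", "mediated",
                          "confounded"))
  out <- data.frame(probe_id = candidates$probe_id, gene = candidates$gene,
                    delta_beta_percent = candidates$delta_beta_percent,
                    p = candidates$p, q = NA_real_, candidate = TRUE,
                    n_shared = ifelse(candidates$meqtl_flag == "Y", 0L, NA_integer_),
                    shared_variants = "", status = status,
                    survives = status %in% c("no_shared_variant", "mediated"),
                    category = candidates$category,
                    il1b_direction = candidates$il1b_direction,
                    chromosome = candidates$chromosome,
                    position = candidates$position,
                    stringsAsFactors = FALSE)
  out[order(suppressWarnings(as.numeric(out$chromosome)), out$position), ]
}

#' Run the full classification pipeline
#'
#' `config` is a list (or path to a YAML file) with:
#' \describe{
#'   \item{mode}{`"cohort"` (full pipeline) or `"fixture"` (start from a
#'     candidate table; stages 1-2 replayed from its recorded flags).}
#'   \item{cohort}{Cohort mode: a `simulated_cohort` object, or a list of
#'     file paths `betas`, `genotypes`, `samples`, `cpg_annotation`,
#'     `variant_annotation` (and optionally `reference`).}
#'   \item{candidate_table}{Fixture mode: path to a candidate table, or
#'     `NULL` for the packaged one.}
#'   \item{gene_list}{Path to a curated gene-list YAML, or `NULL` for the
#'     packaged IL-1\eqn{\beta} list.}
#'   \item{params}{Optional overrides: `fdr_alpha` (0.05), `shared_alpha`
#'     (0.05), `cit_alpha` (0.05), `cit_B` (500), `flank_bp` (500000),
#'     `comethylation_window_bp` (100000), `r_threshold` (0.8),
#'     `gate_inflammation_pattern` (FALSE).}
#'   \item{seed}{Integer seed for the causal inference tests.}
#'   \item{out_dir}{Optional output directory for stage tables, the report
#'     JSON and the log.}
#' }
#'
#' @param config Configuration list or YAML path.
#' @return A `pipeline_report`: classification `records`, `counts`, stage
#'   tables, and provenance (config hash, seed). Fully deterministic given
#'   config + seed.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  mode <- config$mode %||% "cohort"
  params <- modifyList(list(fdr_alpha = 0.05, shared_alpha = 0.05,
                            cit_alpha = 0.05, cit_B = 500L, flank_bp = 5e5,
                            comethylation_window_bp = 1e5, r_threshold = 0.8,
                            gate_inflammation_pattern = FALSE),
                       config$params %||% list())
  seed <- as.integer(config$seed %||% 1L)
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    r
  }

  if (mode == "fixture") {
    candidates <- stage("load_candidates", {
      if (is.null(config$candidate_table)) load_gout_candidates()
      else { df <- read.delim(config$candidate_table, sep = "\t",
                              stringsAsFactors = FALSE,
                              colClasses = c(chromosome = "character"))
             validate_candidate_table(df); df }
    })
    records <- stage("classify", classify_candidate_table(candidates))
    report <- new_pipeline_report(records, list(), params, seed, timings,
                                  mode)
    if (!is.null(config$out_dir)) write_report(report, config$out_dir)
    return(report)
  }

  ## cohort mode ------------------------------------------------------------
  ch <- config$cohort
  if (inherits(ch, "simulated_cohort")) {
    betas <- ch$betas; genotypes <- ch$genotypes; samples <- ch$samples
    cpg_anno <- ch$cpg_annotation; var_anno <- ch$variant_annotation
    reference <- ch$panel_reference
  } else {
    betas <- stage("read_betas", read_beta_matrix(ch$betas))
    genotypes <- stage("read_genotypes", read_genotypes(ch$genotypes))
    samples <- stage("read_samples", read_sample_table(ch$samples))
    cpg_anno <- stage("read_cpg_annotation",
                      read_cpg_annotation(ch$cpg_annotation))
    var_anno <- stage("read_variant_annotation",
                      read_variant_annotation(ch$variant_annotation))
    reference <- load_reference_profiles(ch$reference %||% NULL)
  }
  gene_list <- if (is.data.frame(config$gene_list)) config$gene_list
               else load_gene_list(config$gene_list %||% NULL)

  props <- stage("deconvolution",
                 estimate_cell_proportions(betas, reference))
  cell_types <- setdiff(names(props), c("sample_id", "residual_norm"))
  prop_cols <- props[match(samples$sample_id, props$sample_id),
                     cell_types, drop = FALSE]
  names(prop_cols) <- paste0("prop_", cell_types)
  samples <- cbind(samples, prop_cols)

  ewas <- stage("promoter_ewas", promoter_ewas(betas, samples, cpg_anno))
  candidate_flag <- ewas$q < params$fdr_alpha & ewas$gene %in% gene_list$gene
  cand <- ewas[candidate_flag, ]

  traits <- stage("trait_specificity", {
    if (nrow(cand) > 0 &&
        all(c("bmi", "hba1c", "total_cholesterol") %in% names(samples)))
      trait_specificity(betas, samples, cand$probe_id) else NULL
  })
  contrasts <- stage("three_group_contrasts", {
    if (nrow(cand) > 0)
      three_group_contrasts(betas, samples, cand$probe_id) else NULL
  })

  regional <- list(); cit_all <- list()
  records <- list()
  for (i in seq_len(nrow(ewas))) {
    row <- ewas[i, ]
    if (!candidate_flag[i]) {
      records[[row$probe_id]] <- classify_cpg(row, character(0),
                                              cit_result_prototype(),
                                              candidate = FALSE,
                                              alpha_cit = params$cit_alpha)
      next
    }
    win <- cis_window(cpg_anno, row$probe_id, params$flank_bp)
    mq <- stage(paste0("scan_meqtl:", row$probe_id),
                scan_meqtl(betas, genotypes, samples, row$probe_id, win,
                           var_anno))
    ds <- stage(paste0("scan_disease:", row$probe_id),
                scan_disease(genotypes, samples, win, var_anno))
    regional[[row$probe_id]] <- regional_table(mq, ds, params$shared_alpha)
    shared <- find_shared_variants(mq, ds, params$shared_alpha)
    cit <- stage(paste0("cit:", row$probe_id),
                 cit_batch(shared, row$probe_id, betas, genotypes, samples,
                           variant_annotation = var_anno,
                           B = params$cit_B, seed = seed))
    cit_all[[row$probe_id]] <- cit
    records[[row$probe_id]] <- classify_cpg(row, shared, cit,
                                            candidate = TRUE,
                                            alpha_cit = params$cit_alpha)
  }
  records <- do.call(rbind, unname(records))
  records <- merge(records,
                   cpg_anno[, c("probe_id", "chromosome", "position")],
                   by = "probe_id")
  records <- merge(records, gene_list, by = "gene", all.x = TRUE)
  if (!is.null(contrasts)) {
    ip <- unique(contrasts[, c("probe_id", "inflammation_pattern")])
    records <- merge(records, ip, by = "probe_id", all.x = TRUE)
  } else records$inflammation_pattern <- NA
  if (!is.null(traits)) {
    gs <- unique(traits[, c("probe_id", "gout_specific")])
    records <- merge(records, gs, by = "probe_id", all.x = TRUE)
  } else records$gout_specific <- NA
  if (isTRUE(params$gate_inflammation_pattern)) {
    gated <- records$candidate & !is.na(records$inflammation_pattern) &
      !records$inflammation_pattern
    records$status[gated] <- "not_candidate"
    records$candidate[gated] <- FALSE
    records$survives[gated] <- FALSE
  }
  records <- records[order(suppressWarnings(as.numeric(records$chromosome)),
                           records$position, records$probe_id), ]
  rownames(records) <- NULL

  cometh <- stage("comethylation", {
    surv <- records$probe_id[records$survives]
    if (length(surv) == 0) NULL
    else do.call(rbind, lapply(surv, function(p)
      comethylation_neighbors(betas, samples, cpg_anno, p,
                              window_bp = params$comethylation_window_bp,
                              r_threshold = params$r_threshold)))
  })

  # structural invariant: a survivor has no shared variant or all CIT pass
  ok <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    if (!r$survives) return(TRUE)
    if (r$n_shared == 0) return(TRUE)
    cr <- cit_all[[r$probe_id]]
    all(cr$p_omnibus < params$cit_alpha)
  }, logical(1))
  stopifnot(all(ok))

  report <- new_pipeline_report(records,
                                list(proportions = props, ewas = ewas,
                                     traits = traits, contrasts = contrasts,
                                     regional = regional, cit = cit_all,
                                     comethylation = cometh),
                                params, seed, timings, mode)
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

new_pipeline_report <- function(records, stages, params, seed, timings,
                                mode) {
  counts <- list(
    n_tested = nrow(records),
    n_candidates = sum(records$candidate),
    n_survivors = sum(records$survives),
    n_no_shared_variant = sum(records$status == "no_shared_variant"),
    n_mediated = sum(records$status == "mediated"),
    n_confounded = sum(records$status == "confounded"),
    n_not_candidate = sum(records$status == "not_candidate"))
  provenance <- list(package_version = as.character(utils::packageVersion("methgout")),
                     mode = mode, seed = seed,
                     config_hash = hash_of(list(params = params, seed = seed,
                                                mode = mode)),
                     params = params)
  structure(list(records = records, counts = counts, stages = stages,
                 provenance = provenance, timings = timings),
            class = "pipeline_report")
}

hash_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(x), f)
  unname(tools::md5sum(f))
}

#' Summarize a pipeline report
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @return One-row data frame: candidate/survivor/status counts, the minimum
#'   and maximum absolute methylation difference (percent) among survivors,
#'   and survivor counts by category (IL-1\eqn{\beta}-related vs previously
#'   implicated in gouty inflammation).
#' @export
summarize_report <- function(report) {
  stopifnot(inherits(report, "pipeline_report"))
  r <- report$records
  surv <- r[r$survives, , drop = FALSE]
  cat_col <- if ("category" %in% names(r)) r$category else rep(NA, nrow(r))
  il1b <- c("il1b_production", "expressed_macrophage_il1b")
  data.frame(
    n_candidates = sum(r$candidate),
    n_survivors = nrow(surv),
    n_no_shared_variant = sum(r$status == "no_shared_variant"),
    n_mediated = sum(r$status == "mediated"),
    n_confounded = sum(r$status == "confounded"),
    min_abs_delta_beta_percent = if (nrow(surv) > 0)
      min(abs(surv$delta_beta_percent)) else NA_real_,
    max_abs_delta_beta_percent = if (nrow(surv) > 0)
      max(abs(surv$delta_beta_percent)) else NA_real_,
    n_survivors_il1b = sum(surv$category %in% il1b, na.rm = TRUE),
    n_survivors_gouty_inflammation =
      sum(surv$category == "gouty_inflammation", na.rm = TRUE),
    stringsAsFactors = FALSE)
}

#' Write a pipeline report to a directory
#'
#' Writes the classification table, all stage tables, a deterministic JSON
#' report (counts, records, provenance; byte-identical for identical
#' config + seed) and a log with stage timings.
#'
#' @param report A `pipeline_report`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_results_table(report$records,
                      file.path(out_dir, "classification.tsv"))
  st <- report$stages
  if (!is.null(st$proportions))
    write_results_table(st$proportions,
                        file.path(out_dir, "cell_proportions.tsv"))
  if (!is.null(st$ewas))
    write_results_table(st$ewas, file.path(out_dir, "promoter_ewas.tsv"))
  if (!is.null(st$traits))
    write_results_table(st$traits,
                        file.path(out_dir, "trait_specificity.tsv"))
  if (!is.null(st$contrasts))
    write_results_table(st$contrasts,
                        file.path(out_dir, "urate_contrasts.tsv"))
  for (p in names(st$regional))
    write_results_table(st$regional[[p]],
                        file.path(out_dir, sprintf("regional_%s.tsv", p)))
  cit <- if (length(st$cit) > 0) do.call(rbind, unname(st$cit)) else NULL
  if (!is.null(cit) && nrow(cit) > 0)
    write_results_table(cit, file.path(out_dir, "cit_results.tsv"))
  if (!is.null(st$comethylation) && nrow(st$comethylation) > 0)
    write_results_table(st$comethylation,
                        file.path(out_dir, "comethylation.tsv"))
  json <- list(counts = report$counts, summary = summarize_report(report),
               records = report$records, provenance = report$provenance)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(sprintf("seed: %d", report$provenance$seed),
               sprintf("config_hash: %s", report$provenance$config_hash),
               sprintf("stage %s: %.3fs", names(report$timings),
                       unlist(report$timings))),
             file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report (%s mode): %d probes, %d candidates, %d survivors\n",
              x$provenance$mode, x$counts$n_tested, x$counts$n_candidates,
              x$counts$n_survivors))
  cat(sprintf("  no_shared_variant %d | mediated %d | confounded %d\n",
              x$counts$n_no_shared_variant, x$counts$n_mediated,
              x$counts$n_confounded))
  invisible(x)
}

#' Agreement between pipeline classifications and simulation truth
#'
#' @param report A `pipeline_report` from a cohort-mode run.
#' @param truth Truth table from [scenario_truth_table()].
#' @return Named list: per-probe agreement fraction and the merged table.
#' @export
classification_agreement <- function(report, truth) {
  m <- merge(report$records[, c("probe_id", "status")],
             truth[, c("probe_id", "expected_classification")],
             by = "probe_id")
  list(agreement = mean(m$status == m$expected_classification),
       all_match = all(m$status == m$expected_classification),
       table = m)
}
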