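#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set for [simulate_cohort()]. The
#' generator emulates a case/control blood-methylation cohort with
#' cell-mixture structure, cis genetic effects on methylation, covariate
#' effects, and one configurable causal structure per target CpG:
#' `"independent"` (methylation differs by disease status with no genetic
#' driver), `"mediation"` (variant affects disease only through methylation),
#' `"confounding"` (variant affects methylation and disease independently),
#' or `"null"` (no signal).
#'
#' All methylation effects are additive on the logit-beta scale and mapped
#' back through the inverse logit, which keeps betas in the unit interval
#' while permitting case-control differences below one percent. Disease
#' status is drawn from a logistic model whose intercept is calibrated by
#' bisection so that the expected prevalence matches `prevalence`.
#'
#' @param n_samples Cohort size.
#' @param scenarios Character vector, one causal scenario per target CpG.
#' @param n_null_cpgs Number of additional promoter CpGs with no signal.
#' @param n_cell_types Number of leukocyte subsets in the mixture.
#' @param dirichlet_alpha Dirichlet concentration vector for cell
#'   proportions (length `n_cell_types`).
#' @param maf Minor-allele frequency of causal variants, in (0, 0.5].
#' @param meqtl_effect Per-allele shift of the target CpG on the logit-beta
#'   scale.
#' @param disease_effect_methylation Gout log-odds per unit beta (mediation
#'   CpGs; disease depends on the observed methylation only).
#' @param disease_effect_variant Gout log-odds per allele (confounding CpGs).
#' @param delta_beta_target Case-minus-control methylation difference on the
#'   beta scale injected at "independent" CpGs.
#' @param covariate_effects List with numeric vectors `methylation` and
#'   `gout` giving coefficients of sex, centered age, pack-years, alcohol and
#'   smoking-status dummies on logit-beta and on the gout log-odds.
#' @param noise_sd Logit-normal measurement/biological noise SD.
#' @param prevalence Target gout prevalence (intercept calibrated to it).
#' @param hyper_fraction Fraction of non-gout samples labelled hyperuricemia;
#'   methylation does not depend on this split.
#' @param n_decoy_variants Cis variants with no effect added per target CpG.
#' @param n_causal_variants Causal variants per mediation/confounding CpG.
#' @param cell_confounding Gout log-odds per SD of the first cell-type
#'   proportion (0 disables cell-mixture confounding).
#' @param panel_noise_sd Logit noise SD for the deconvolution panel probes.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 1524,
                              scenarios = c("independent", "mediation",
                                            "confounding"),
                              n_null_cpgs = 20,
                              n_cell_types = 6,
                              dirichlet_alpha = c(30, 7.5, 5, 2.5, 3.5, 1.5),
                              maf = 0.4,
                              meqtl_effect = 0.8,
                              disease_effect_methylation = 3,
                              disease_effect_variant = 0.7,
                              delta_beta_target = 0.01,
                              covariate_effects = NULL,
                              noise_sd = 0.45,
                              prevalence = 0.045,
                              hyper_fraction = 0.25,
                              n_decoy_variants = 10,
                              n_causal_variants = 1,
                              cell_confounding = 0,
                              panel_noise_sd = 0.05,
                              seed = 1L) {
  if (is.null(covariate_effects)) {
    covariate_effects <- list(
      methylation = c(sex = -0.05, age = 0.005, pack_years = 0.002,
                      alcohol = 0.05, smoking_former = 0.05,
                      smoking_current = 0.10),
      gout = c(sex = 1.2, age = 0.02, pack_years = 0.01, alcohol = 0.3,
               smoking_former = 0.1, smoking_current = 0.2))
  }
  cfg <- list(n_samples = as.integer(n_samples), scenarios = scenarios,
              n_null_cpgs = as.integer(n_null_cpgs),
              n_cell_types = as.integer(n_cell_types),
              dirichlet_alpha = dirichlet_alpha, maf = maf,
              meqtl_effect = meqtl_effect,
              disease_effect_methylation = disease_effect_methylation,
              disease_effect_variant = disease_effect_variant,
              delta_beta_target = delta_beta_target,
              covariate_effects = covariate_effects, noise_sd = noise_sd,
              prevalence = prevalence, hyper_fraction = hyper_fraction,
              n_decoy_variants = as.integer(n_decoy_variants),
              n_causal_variants = as.integer(n_causal_variants),
              cell_confounding = cell_confounding,
              panel_noise_sd = panel_noise_sd, seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_samples < 10) stop("n_samples must be at least 10")
  bad <- setdiff(cfg$scenarios,
                 c("independent", "mediation", "confounding", "null"))
  if (length(bad) > 0) stop("unknown scenario: ", paste(bad, collapse = ", "))
  if (cfg$maf <= 0 || cfg$maf > 0.5)
    stop("maf must lie in (0, 0.5]")
  if (length(cfg$dirichlet_alpha) != cfg$n_cell_types)
    stop("dirichlet_alpha must have length n_cell_types")
  if (any(cfg$dirichlet_alpha <= 0)) stop("dirichlet_alpha must be positive")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  if (cfg$prevalence <= 0 || cfg$prevalence >= 1)
    stop("prevalence must lie in (0, 1)")
  if (cfg$hyper_fraction < 0 || cfg$hyper_fraction > 1)
    stop("hyper_fraction must lie in [0, 1]")
  if (cfg$n_causal_variants < 1) stop("n_causal_variants must be >= 1")
  invisible(cfg)
}

#' Simulate a gout methylation cohort
#'
#' Generates a seeded cohort with the statistical structure assumed by the
#' analysis pipeline: Dirichlet cell proportions, per-cell-type reference
#' methylomes drawn once per seed, proportion-weighted baseline betas,
#' scenario effects on the logit scale, a covariate-driven logistic disease
#' model calibrated to the configured prevalence, and a urate grouping in
#' which methylation does not depend on the normouricemia/hyperuricemia
#' split. Random streams are split per component (and per CpG), so adding
#' CpGs does not perturb earlier draws.
#'
#' @param config A [simulation_config()].
#' @return A `simulated_cohort` list with elements `betas`, `genotypes`,
#'   `samples`, `cpg_annotation`, `variant_annotation`, `panel_reference`,
#'   `truth`, `truth_proportions`, and `config`.
#' @export
simulate_cohort <- function(config) {
  validate_simulation_config(config)
  n <- config$n_samples
  K <- config$n_cell_types
  scen <- config$scenarios
  n_targets <- length(scen)

  seeds <- withr::with_seed(config$seed,
                            sample.int(.Machine$integer.max - 1L, 10L))
  names(seeds) <- c("covariates", "proportions", "references", "genotypes",
                    "noise", "phenotype", "split", "panel", "traits", "spare")

  sample_ids <- sprintf("S%05d", seq_len(n))

  ## covariates -------------------------------------------------------------
  cov <- withr::with_seed(seeds[["covariates"]], {
    sex <- rbinom(n, 1, 0.5)
    age <- round(pmin(pmax(rnorm(n, 49.3, 11.1), 20), 90), 1)
    smoking <- sample(c("never", "former", "current"), n, replace = TRUE,
                      prob = c(0.70, 0.15, 0.15))
    pack_years <- ifelse(smoking == "never", 0, round(rexp(n, 1 / 15), 1))
    alcohol <- rbinom(n, 1, 0.15)
    data.frame(sex = sex, age = age, smoking_status = smoking,
               pack_years = pack_years, alcohol = alcohol,
               stringsAsFactors = FALSE)
  })
  cov_design <- cbind(sex = cov$sex, age = cov$age - 50,
                      pack_years = cov$pack_years, alcohol = cov$alcohol,
                      smoking_former = as.numeric(cov$smoking_status == "former"),
                      smoking_current = as.numeric(cov$smoking_status == "current"))

  ## cell proportions -------------------------------------------------------
  W <- withr::with_seed(seeds[["proportions"]], {
    g <- matrix(rgamma(n * K, shape = rep(config$dirichlet_alpha, each = n)),
                n, K)
    g / rowSums(g)
  })
  cell_names <- if (K == 6) c("Gran", "CD4T", "CD8T", "Bcell", "Mono", "NK")
                else sprintf("cell%02d", seq_len(K))
  colnames(W) <- cell_names
  rownames(W) <- sample_ids

  ## analysis CpGs: annotation and per-seed reference methylomes ------------
  target_ids <- sprintf("cg_sim_t%02d", seq_len(n_targets))
  null_ids <- if (config$n_null_cpgs > 0)
    sprintf("cg_sim_n%03d", seq_len(config$n_null_cpgs)) else character(0)
  probe_ids <- c(target_ids, null_ids)
  n_cpgs <- length(probe_ids)
  scen_all <- c(scen, rep("null", config$n_null_cpgs))

  anno <- data.frame(
    probe_id = probe_ids,
    chromosome = c(as.character(seq_len(n_targets)),
                   rep("20", config$n_null_cpgs)),
    position = c(rep(5e7, n_targets),
                 if (config$n_null_cpgs > 0)
                   3e7 + seq_len(config$n_null_cpgs) * 1e6 else numeric(0)),
    gene = c(sprintf("SIMG%02d", seq_len(n_targets)),
             if (config$n_null_cpgs > 0)
               sprintf("NULLG%03d", seq_len(config$n_null_cpgs))
             else character(0)),
    genomic_feature = c(rep("TSS200", n_targets),
                        rep(PROMOTER_FEATURES,
                            length.out = config$n_null_cpgs)),
    cpg_island = c(rep(TRUE, n_targets), rep(FALSE, config$n_null_cpgs)),
    stringsAsFactors = FALSE)

  # per-CpG substreams keep earlier draws stable when CpGs are added.
  # Target CpGs get intermediate baselines (differentially methylated hits
  # are variable, mid-range probes; saturated baselines cannot express
  # percent-scale group differences); null probes span a wider range.
  ref_profiles <- vapply(seq_len(n_cpgs), function(j) {
    withr::with_seed(seeds[["references"]] %% 1000000L + j, {
      mu <- if (j <= n_targets) runif(1, 0.35, 0.65) else runif(1, 0.2, 0.8)
      plogis(logit(mu) + rnorm(K, 0, 0.5))
    })
  }, numeric(K))                                   # K x n_cpgs

  base <- W %*% ref_profiles                       # n x n_cpgs
  colnames(base) <- probe_ids

  ## genotypes: causal + decoy variants per target CpG ----------------------
  variant_rows <- list()
  dosage_cols <- list()
  causal_of <- setNames(vector("list", n_targets), target_ids)
  v_counter <- 0L
  for (j in seq_len(n_targets)) {
    n_causal <- if (scen[j] %in% c("mediation", "confounding"))
      config$n_causal_variants else 0L
    n_var <- n_causal + config$n_decoy_variants
    if (n_var == 0) next
    mafs <- withr::with_seed(seeds[["genotypes"]] %% 1000000L + 2L * j,
                             c(rep(config$maf, n_causal),
                               runif(config$n_decoy_variants, 0.05, 0.5)))
    dos <- withr::with_seed(seeds[["genotypes"]] %% 1000000L + 2L * j + 1L,
                            vapply(mafs, function(m) rbinom(n, 2, m),
                                   numeric(n)))
    ids <- sprintf("rs%08d", v_counter + seq_len(n_var))
    v_counter <- v_counter + n_var
    pos <- anno$position[j] +
      c(if (n_causal > 0) seq_len(n_causal) * 5000 else numeric(0),
        seq(-450000, 450000, length.out = config$n_decoy_variants))
    variant_rows[[j]] <- data.frame(
      variant_id = ids, chromosome = anno$chromosome[j],
      position = round(pos), ref = "A", alt = "G",
      maf = mafs, cpg = target_ids[j], stringsAsFactors = FALSE)
    colnames(dos) <- ids
    dosage_cols[[j]] <- dos
    if (n_causal > 0) causal_of[[target_ids[j]]] <- ids[seq_len(n_causal)]
  }
  variant_annotation <- do.call(rbind, variant_rows)
  genotypes <- do.call(cbind, dosage_cols)
  rownames(genotypes) <- sample_ids

  ## methylation assembly ---------------------------------------------------
  lg <- logit(squeeze_beta(base))
  lg <- lg + drop(cov_design %*% config$covariate_effects$methylation)
  for (j in seq_len(n_targets)) {
    cv <- causal_of[[target_ids[j]]]
    if (length(cv) > 0)
      lg[, j] <- lg[, j] +
        config$meqtl_effect * rowSums(genotypes[, cv, drop = FALSE])
  }
  if (config$noise_sd > 0) {
    eps <- vapply(seq_len(n_cpgs), function(j)
      withr::with_seed(seeds[["noise"]] %% 1000000L + j,
                       rnorm(n, 0, config$noise_sd)),
      numeric(n))
    lg <- lg + eps
  }
  betas <- plogis(lg)
  dimnames(betas) <- list(sample_ids, probe_ids)

  ## disease model (depends on OBSERVED methylation for mediation CpGs) -----
  lp <- drop(cov_design %*% config$covariate_effects$gout)
  for (j in seq_len(n_targets)) {
    if (scen[j] == "mediation")
      lp <- lp + config$disease_effect_methylation * betas[, j]
    if (scen[j] == "confounding") {
      cv <- causal_of[[target_ids[j]]]
      lp <- lp + config$disease_effect_variant *
        rowSums(genotypes[, cv, drop = FALSE])
    }
  }
  if (config$cell_confounding != 0)
    lp <- lp + config$cell_confounding * as.numeric(scale(W[, 1]))
  icpt <- calibrate_intercept(lp, config$prevalence)
  gout <- withr::with_seed(seeds[["phenotype"]],
                           as.integer(runif(n) < plogis(icpt + lp)))

  ## "independent" CpGs: direct case shift, no genetic driver ---------------
  for (j in seq_len(n_targets)) {
    if (scen[j] != "independent") next
    slope <- mean(betas[, j] * (1 - betas[, j]))
    shift <- config$delta_beta_target / slope
    cases <- gout == 1
    betas[cases, j] <- plogis(logit(squeeze_beta(betas[cases, j])) + shift)
  }

  ## urate grouping: methylation does not depend on the normo/hyper split ---
  hyper <- withr::with_seed(seeds[["split"]],
                            runif(n) < config$hyper_fraction)
  urate_group <- ifelse(gout == 1, "gout",
                        ifelse(hyper, "hyperuricemia", "normouricemia"))

  ## metabolic traits (associated with gout, not with target methylation) ---
  traits <- withr::with_seed(seeds[["traits"]], data.frame(
    bmi = round(rnorm(n, 24.26, 3.57) + 1.79 * gout, 2),
    hba1c = round(rnorm(n, 5.71, 0.73) + 0.25 * gout, 2),
    total_cholesterol = round(rnorm(n, 195, 35) + 5 * gout, 1)))

  samples <- data.frame(sample_id = sample_ids, sex = cov$sex, age = cov$age,
                        pack_years = cov$pack_years,
                        smoking_status = cov$smoking_status,
                        alcohol = cov$alcohol, gout = gout,
                        urate_group = urate_group, traits,
                        stringsAsFactors = FALSE)
  validate_sample_table(samples)

  ## deconvolution panel probes ---------------------------------------------
  panel_reference <- if (K == 6) load_reference_profiles()
                     else synth_panel_reference(K, cell_names,
                                                seeds[["panel"]])
  panel_base <- W %*% t(panel_reference)
  panel_betas <- withr::with_seed(seeds[["panel"]] %% 1000000L + 1L,
    plogis(logit(squeeze_beta(panel_base)) +
           matrix(rnorm(length(panel_base), 0, config$panel_noise_sd),
                  nrow(panel_base))))
  dimnames(panel_betas) <- list(sample_ids, rownames(panel_reference))
  betas <- cbind(betas, panel_betas)
  panel_anno <- data.frame(
    probe_id = rownames(panel_reference), chromosome = "21",
    position = 1e6 + seq_len(nrow(panel_reference)) * 1000,
    gene = "", genomic_feature = "Body", cpg_island = FALSE,
    stringsAsFactors = FALSE)
  anno <- rbind(anno, panel_anno)
  validate_beta_matrix(betas)
  validate_cpg_annotation(anno)

  ## ground truth -----------------------------------------------------------
  realized <- colMeans(betas[gout == 1, probe_ids, drop = FALSE]) -
    colMeans(betas[gout == 0, probe_ids, drop = FALSE])
  truth <- data.frame(
    probe_id = probe_ids, scenario = scen_all,
    generative_delta_beta = ifelse(scen_all == "independent",
                                   config$delta_beta_target,
                                   ifelse(scen_all == "null", 0, NA_real_)),
    realized_delta_beta = as.numeric(realized),
    causal_variants = vapply(probe_ids, function(p) {
      cv <- causal_of[[p]]
      if (is.null(cv) || length(cv) == 0) "" else paste(cv, collapse = ",")
    }, character(1)),
    expected_classification = unname(c(independent = "no_shared_variant",
                                       mediation = "mediated",
                                       confounding = "confounded",
                                       null = "not_candidate")[scen_all]),
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(betas = betas, genotypes = genotypes, samples = samples,
                 cpg_annotation = anno,
                 variant_annotation = variant_annotation,
                 panel_reference = panel_reference, truth = truth,
                 truth_proportions = W, config = config),
            class = "simulated_cohort")
}

# Synthetic K-cell-type panel in the same one-subset-low design as the
# packaged reference, for non-default cell-type counts.
synth_panel_reference <- function(K, cell_names, seed, n_probes = 300L) {
  withr::with_seed(seed, {
    R <- matrix(runif(n_probes * K, 0.70, 0.95), n_probes, K)
    low_in <- rep(seq_len(K), length.out = n_probes)
    for (j in seq_len(n_probes)) R[j, low_in[j]] <- runif(1, 0.05, 0.25)
    dimnames(R) <- list(sprintf("dp%05d", seq_len(n_probes)), cell_names)
    R
  })
}

# Calibrate the logistic intercept so mean predicted prevalence hits the
# target; bisection, deterministic.
calibrate_intercept <- function(lp, prevalence) {
  f <- function(c) mean(plogis(c + lp)) - prevalence
  uniroot(f, interval = c(-40, 40), tol = 1e-10)$root
}

#' Expected classification for every simulated CpG
#'
#' @param cohort A `simulated_cohort` from [simulate_cohort()].
#' @return Data frame with `probe_id`, `scenario`, `expected_classification`.
#' @export
scenario_truth_table <- function(cohort) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  cohort$truth[, c("probe_id", "scenario", "expected_classification")]
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf(
    "simulated_cohort: %d samples (%d gout), %d CpGs (+%d panel probes), %d variants\n",
    nrow(x$betas), sum(x$samples$gout), nrow(x$truth),
    ncol(x$betas) - nrow(x$truth), ncol(x$genotypes)))
  cat("scenarios:", paste(sprintf("%s=%s", x$truth$probe_id[
    x$truth$scenario != "null"], x$truth$scenario[x$truth$scenario != "null"]),
    collapse = ", "), "\n")
  invisible(x)
}

#' Write all cohort artifacts to a directory
#'
#' Writes the beta matrix, genotype dosages, sample sheet, CpG and variant
#' annotation, panel reference, and truth table in the package's
#' tab-separated dialects, with a provenance header carrying the seed.
#'
#' @param cohort A `simulated_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_beta_matrix(cohort$betas, file.path(dir, "betas.tsv"))
  write_genotype_matrix(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  write_results_table(cohort$samples, file.path(dir, "samples.tsv"))
  write_results_table(cohort$cpg_annotation,
                      file.path(dir, "cpg_annotation.tsv"))
  write_results_table(cohort$variant_annotation,
                      file.path(dir, "variant_annotation.tsv"))
  write_id_matrix(cohort$panel_reference,
                  file.path(dir, "panel_reference.tsv"), "probe_id",
                  digits = 4L)
  write_results_table(cohort$truth, file.path(dir, "truth.tsv"))
  writeLines(c(sprintf("seed: %d", cohort$config$seed),
               sprintf("n_samples: %d", cohort$config$n_samples)),
             file.path(dir, "provenance.txt"))
  invisible(dir)
}
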