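# Default adjustment set: sex, age, smoking history (total pack-years),
# smoking status, alcohol consumption, plus estimated blood cell subsets
# when proportion columns are present.
DEFAULT_COVARIATES <- c("sex", "age", "pack_years", "smoking_status", "alcohol")

# Build the covariate design matrix (no intercept column; lm adds its own).
# Smoking status enters as dummies with "never" as reference. Cell
# proportion columns (prop_*) enter all but the first (reference subset) to
# avoid collinearity with the intercept when proportions sum to ~1.
# Collinear columns raise an error naming the offenders.
build_covariate_design <- function(samples, covariate_set = DEFAULT_COVARIATES,
                                   cell_props = TRUE) {
  cols <- list()
  for (cv in covariate_set) {
    if (!cv %in% names(samples))
      stop("covariate column missing from sample table: ", cv)
    if (cv == "smoking_status") {
      cols[["smoking_former"]] <- as.numeric(samples$smoking_status == "former")
      cols[["smoking_current"]] <- as.numeric(samples$smoking_status == "current")
    } else {
      v <- samples[[cv]]
      if (!is.numeric(v)) stop("covariate must be numeric: ", cv)
      cols[[cv]] <- v
    }
  }
  if (cell_props) {
    props <- grep("^prop_", names(samples), value = TRUE)
    for (pc in props[-1L][seq_len(max(0, length(props) - 1L))])
      cols[[pc]] <- samples[[pc]]
  }
  X <- do.call(cbind, cols)
  if (is.null(X)) return(matrix(numeric(0), nrow(samples), 0))
  rownames(X) <- samples$sample_id
  # drop constant columns silently only if they carry no information;
  # a constant covariate the user asked for is an error
  const <- apply(X, 2, function(v) var(v, na.rm = TRUE) == 0 || all(is.na(v)))
  if (any(const))
    X <- X[, !const, drop = FALSE]
  if (ncol(X) > 1) {
    q <- qr(cbind(1, X[complete.cases(X), , drop = FALSE]))
    if (q$rank < ncol(X) + 1) {
      aliased <- colnames(X)[q$pivot[seq(q$rank + 1, ncol(X) + 1)] - 1L]
      cc <- cor(X, use = "pairwise.complete.obs")
      diag(cc) <- 0
      partner <- colnames(X)[apply(abs(cc[aliased, , drop = FALSE]), 1,
                                   which.max)]
      stop("collinear covariates: ",
           paste(aliased, partner, sep = " ~ ", collapse = ", "))
    }
  }
  X
}

#' Per-CpG association of methylation with an outcome
#'
#' Ordinary least squares of the probe's beta values on the outcome plus the
#' adjustment covariates (`methylation ~ outcome + covariates`). For the
#' binary gout flag (coded 0/1) the outcome coefficient is exactly the
#' covariate-adjusted case-minus-control methylation difference
#' \eqn{\Delta\beta}; the p-value is the coefficient's two-sided t-test.
#' Complete-case per probe.
#'
#' @param betas Samples-by-probes beta matrix.
#' @param samples Sample table (see [read_sample_table()]); cell-proportion
#'   columns named `prop_*` are used as covariates when present.
#' @param probe_id Probe to test.
#' @param outcome Name of the outcome column in `samples` (default `"gout"`)
#'   — binary 0/1 or a continuous trait.
#' @param covariate_set Covariate columns to adjust for; `smoking_status`
#'   expands to former/current dummies against a never-smoker reference.
#' @param use_m_values Regress on logit2-transformed betas instead of betas
#'   (off by default so the coefficient stays on the beta scale).
#' @return One-row data frame: `probe_id`, `outcome`, `delta_beta`, `se`,
#'   `statistic`, `p`, `n_used` (`q` is left unset).
#' @export
fit_cpg_association <- function(betas, samples, probe_id, outcome = "gout",
                                covariate_set = DEFAULT_COVARIATES,
                                use_m_values = FALSE) {
  if (!probe_id %in% colnames(betas))
    stop("probe not present in beta matrix: ", probe_id)
  if (!outcome %in% names(samples))
    stop("outcome column missing from sample table: ", outcome)
  idx <- match(samples$sample_id, rownames(betas))
  if (anyNA(idx))
    stop("sample table contains ids absent from the beta matrix: ",
         samples$sample_id[which(is.na(idx))[1L]])
  y <- betas[idx, probe_id]
  if (use_m_values) y <- log2(squeeze_beta(y) / (1 - squeeze_beta(y)))
  x <- samples[[outcome]]
  if (!is.numeric(x)) stop("outcome must be numeric: ", outcome)
  if (var(x, na.rm = TRUE) == 0)
    stop("degenerate outcome: ", outcome, " is constant")
  X <- build_covariate_design(samples, covariate_set)
  keep <- complete.cases(cbind(y, x, X))
  n_used <- sum(keep)
  if (n_used < 10 + ncol(X) + 2)
    stop(sprintf("too few complete cases (%d) for probe %s", n_used, probe_id))
  yk <- y[keep]
  if (var(yk) == 0) stop("degenerate probe: ", probe_id,
                         " has constant methylation")
  df <- data.frame(y = yk, x = x[keep])
  if (ncol(X) > 0) df <- cbind(df, as.data.frame(X[keep, , drop = FALSE]))
  fit <- lm(y ~ ., data = df)
  cf <- summary(fit)$coefficients
  if (!"x" %in% rownames(cf))
    stop("outcome aliased with covariates for probe ", probe_id)
  data.frame(probe_id = probe_id, outcome = outcome,
             delta_beta = cf["x", "Estimate"], se = cf["x", "Std. Error"],
             statistic = cf["x", "t value"], p = cf["x", "Pr(>|t|)"],
             n_used = n_used, stringsAsFactors = FALSE)
}

#' Promoter-restricted EWAS with false-discovery control
#'
#' Restricts to CpGs annotated to promoter features (TSS1500, TSS200,
#' 5'UTR), fits [fit_cpg_association()] per probe against the gout flag with
#' the full covariate set, and applies Benjamini-Hochberg adjustment across
#' exactly the tested promoter probes.
#'
#' @inheritParams fit_cpg_association
#' @param annotation CpG annotation covering the probes.
#' @return Data frame, one row per promoter probe, with `delta_beta`, `se`,
#'   `p`, `q`, `n_used`, `chromosome`, `position`, `gene`, and `neg_log10_p`,
#'   ordered by chromosome and position.
#' @export
promoter_ewas <- function(betas, samples, annotation, outcome = "gout",
                          covariate_set = DEFAULT_COVARIATES) {
  validate_cpg_annotation(annotation)
  promo <- annotation[annotation$genomic_feature %in% PROMOTER_FEATURES &
                        annotation$probe_id %in% colnames(betas), ]
  if (nrow(promo) == 0)
    stop("no promoter CpGs (TSS1500/TSS200/5UTR) among the probes")
  res <- do.call(rbind, lapply(promo$probe_id, function(p)
    fit_cpg_association(betas, samples, p, outcome, covariate_set)))
  res$q <- p.adjust(res$p, method = "BH")
  res <- merge(res, promo[, c("probe_id", "chromosome", "position", "gene",
                              "genomic_feature")], by = "probe_id")
  res$neg_log10_p <- -log10(res$p)
  res[order(res$chromosome, res$position, res$probe_id), ]
}

#' Metabolic-trait specificity screen
#'
#' Regresses each candidate probe's methylation on BMI, HbA1c and total
#' cholesterol (continuous outcomes, same covariate adjustment). A probe is
#' flagged gout-specific when all three trait p-values are at or above 0.05.
#'
#' @inheritParams fit_cpg_association
#' @param probes Probes to screen.
#' @param traits Trait columns to test.
#' @return Data frame of per-(probe, trait) results plus a per-probe
#'   `gout_specific` flag repeated across its rows.
#' @export
trait_specificity <- function(betas, samples, probes,
                              traits = c("bmi", "hba1c", "total_cholesterol"),
                              covariate_set = DEFAULT_COVARIATES) {
  miss <- setdiff(traits, names(samples))
  if (length(miss) > 0)
    stop("trait column(s) missing from sample table: ",
         paste(miss, collapse = ", "))
  res <- do.call(rbind, lapply(probes, function(pr)
    do.call(rbind, lapply(traits, function(tr)
      fit_cpg_association(betas, samples, pr, outcome = tr,
                          covariate_set = covariate_set)))))
  spec <- tapply(res$p >= 0.05, res$probe_id, all)
  res$gout_specific <- as.logical(spec[res$probe_id])
  res
}

#' Three-group urate contrasts
#'
#' For each probe, two covariate-adjusted pairwise contrasts of methylation:
#' normouricemia vs hyperuricemia, and hyperuricemia vs gout. A probe shows
#' the gouty-inflammation pattern when methylation is flat across the
#' normouricemia-to-hyperuricemia transition (p >= 0.05) but shifts in the
#' hyperuricemia-to-gout transition (p < 0.05).
#'
#' @inheritParams fit_cpg_association
#' @param probes Probes to contrast.
#' @param min_group Minimum samples per urate group; probes are skipped with
#'   a warning below it.
#' @return Data frame with one row per (probe, contrast) and a per-probe
#'   `inflammation_pattern` flag.
#' @export
three_group_contrasts <- function(betas, samples, probes,
                                  covariate_set = DEFAULT_COVARIATES,
                                  min_group = 5L) {
  lv <- c("normouricemia", "hyperuricemia", "gout")
  counts <- table(factor(samples$urate_group, levels = lv))
  if (any(counts == 0))
    stop("all three urate groups must be present; missing: ",
         paste(lv[counts == 0], collapse = ", "))
  if (any(counts < min_group)) {
    warning(sprintf("urate group(s) below %d samples (%s); probes skipped",
                    min_group,
                    paste(lv[counts < min_group], collapse = ", ")))
    return(data.frame(probe_id = character(0), contrast = character(0),
                      difference = numeric(0), p = numeric(0),
                      inflammation_pattern = logical(0)))
  }
  one_contrast <- function(pr, groups, name) {
    sub <- samples[samples$urate_group %in% groups, , drop = FALSE]
    sub$contrast_ind <- as.numeric(sub$urate_group == groups[2L])
    r <- fit_cpg_association(betas, sub, pr, outcome = "contrast_ind",
                             covariate_set = covariate_set)
    data.frame(probe_id = pr, contrast = name, difference = r$delta_beta,
               p = r$p, n_used = r$n_used, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, lapply(probes, function(pr) rbind(
    one_contrast(pr, c("normouricemia", "hyperuricemia"), "normo_vs_hyper"),
    one_contrast(pr, c("hyperuricemia", "gout"), "hyper_vs_gout"))))
  flag <- vapply(probes, function(pr) {
    pp <- res[res$probe_id == pr, ]
    pp$p[pp$contrast == "normo_vs_hyper"] >= 0.05 &&
      pp$p[pp$contrast == "hyper_vs_gout"] < 0.05
  }, logical(1))
  res$inflammation_pattern <- as.logical(flag[res$probe_id])
  res
}

#' Co-methylation of neighbouring promoter probes
#'
#' Neighbours are promoter/5'UTR probes of the same gene, or promoter probes
#' within `window_bp` of the target on the same chromosome. For each
#' neighbour: the Pearson correlation with the target across samples, the
#' neighbour's own covariate-adjusted gout-association p-value, and a
#' co-methylation flag at `|r| >= r_threshold`.
#'
#' @inheritParams fit_cpg_association
#' @param annotation CpG annotation covering target and neighbours.
#' @param target_probe The differentially methylated probe of interest.
#' @param window_bp Search window around the target (bp, > 0).
#' @param r_threshold Absolute-correlation threshold for the flag.
#' @return Data frame of neighbours (possibly empty) with `r`, `neighbor_p`,
#'   `comethylated`.
#' @export
comethylation_neighbors <- function(betas, samples, annotation, target_probe,
                                    window_bp = 100000, r_threshold = 0.8,
                                    covariate_set = DEFAULT_COVARIATES) {
  if (window_bp <= 0) stop("window_bp must be positive")
  if (!target_probe %in% annotation$probe_id ||
      !target_probe %in% colnames(betas))
    stop("target probe absent from annotation or beta matrix: ", target_probe)
  ta <- annotation[annotation$probe_id == target_probe, ]
  cand <- annotation[annotation$probe_id != target_probe &
                       annotation$genomic_feature %in% PROMOTER_FEATURES &
                       annotation$probe_id %in% colnames(betas), ]
  near <- (cand$gene == ta$gene & nzchar(ta$gene)) |
    (cand$chromosome == ta$chromosome &
       abs(cand$position - ta$position) <= window_bp)
  nb <- cand[near, ]
  if (nrow(nb) == 0) {
    message("no promoter neighbours found for ", target_probe)
    return(data.frame(target = character(0), neighbor = character(0),
                      r = numeric(0), neighbor_p = numeric(0),
                      comethylated = logical(0)))
  }
  idx <- match(samples$sample_id, rownames(betas))
  tv <- betas[idx, target_probe]
  rows <- lapply(nb$probe_id, function(p) {
    r <- suppressWarnings(cor(tv, betas[idx, p],
                              use = "pairwise.complete.obs"))
    gp <- fit_cpg_association(betas, samples, p,
                              covariate_set = covariate_set)$p
    data.frame(target = target_probe, neighbor = p, r = r, neighbor_p = gp,
               comethylated = !is.na(r) && abs(r) >= r_threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
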