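#' Cis window around a CpG
#'
#' @param annotation CpG annotation containing `probe_id`.
#' @param probe_id CpG anchoring the window.
#' @param flank_bp Flank on each side (default 500 kb).
#' @return List with `chromosome`, `start`, `end` (1-based, inclusive) and
#'   `probe_id`.
#' @export
cis_window <- function(annotation, probe_id, flank_bp = 500000) {
  a <- annotation[annotation$probe_id == probe_id, ]
  if (nrow(a) != 1) stop("probe not in annotation: ", probe_id)
  list(probe_id = probe_id, chromosome = a$chromosome,
       start = max(1, a$position - flank_bp), end = a$position + flank_bp)
}

variants_in_window <- function(variant_annotation, window) {
  v <- variant_annotation[variant_annotation$chromosome == window$chromosome &
                            variant_annotation$position >= window$start &
                            variant_annotation$position <= window$end, ]
  v[order(v$position, v$variant_id), ]
}

#' Cis-meQTL scan for one CpG
#'
#' Per variant in the cis window, linear regression of the CpG's methylation
#' on the additive dosage plus the adjustment covariates; two-sided t-test
#' p-value for the dosage coefficient. Monomorphic variants are skipped with
#' a message.
#'
#' @param betas Samples-by-probes beta matrix.
#' @param genotypes Samples-by-variants dosage matrix.
#' @param samples Sample table.
#' @param probe_id Target CpG.
#' @param window Cis window from [cis_window()].
#' @param variant_annotation Variant annotation table.
#' @param covariate_set Covariates to adjust for.
#' @return Data frame of association records (`variant_id`, `target`,
#'   `position`, `effect`, `statistic`, `p`, `n_used`).
#' @export
scan_meqtl <- function(betas, genotypes, samples, probe_id, window,
                       variant_annotation,
                       covariate_set = DEFAULT_COVARIATES) {
  stopifnot(window$probe_id == probe_id)
  vars <- variants_in_window(variant_annotation, window)
  vars <- vars[vars$variant_id %in% colnames(genotypes), ]
  if (nrow(vars) == 0) stop("no variants in the cis window of ", probe_id)
  idx <- match(samples$sample_id, rownames(betas))
  gidx <- match(samples$sample_id, rownames(genotypes))
  if (anyNA(gidx))
    stop("sample table contains ids absent from the genotype matrix")
  y <- betas[idx, probe_id]
  X <- build_covariate_design(samples, covariate_set)
  rows <- lapply(seq_len(nrow(vars)), function(k) {
    v <- vars$variant_id[k]
    d <- genotypes[gidx, v]
    keep <- complete.cases(cbind(y, d, X))
    if (var(d[keep]) == 0) {
      message("monomorphic variant skipped: ", v)
      return(NULL)
    }
    df <- data.frame(y = y[keep], d = d[keep])
    if (ncol(X) > 0) df <- cbind(df, as.data.frame(X[keep, , drop = FALSE]))
    cf <- summary(lm(y ~ ., data = df))$coefficients
    data.frame(variant_id = v, target = probe_id, position = vars$position[k],
               effect = cf["d", "Estimate"], statistic = cf["d", "t value"],
               p = cf["d", "Pr(>|t|)"], n_used = sum(keep),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("all variants in the window are monomorphic")
  out
}

#' Cis disease scan (variant vs gout)
#'
#' Per variant in the window, logistic regression of the gout flag on dosage
#' plus covariates; Wald p-value for the dosage coefficient. Fits that fail
#' to converge or separate are refit with Firth's penalized likelihood and
#' flagged.
#'
#' @inheritParams scan_meqtl
#' @return Data frame of association records with a `firth` flag.
#' @export
scan_disease <- function(genotypes, samples, window, variant_annotation,
                         covariate_set = DEFAULT_COVARIATES) {
  if (length(unique(samples$gout)) < 2)
    stop("both gout classes must be present")
  vars <- variants_in_window(variant_annotation, window)
  vars <- vars[vars$variant_id %in% colnames(genotypes), ]
  if (nrow(vars) == 0)
    stop("no variants in the cis window of ", window$probe_id)
  gidx <- match(samples$sample_id, rownames(genotypes))
  if (anyNA(gidx))
    stop("sample table contains ids absent from the genotype matrix")
  X <- build_covariate_design(samples, covariate_set)
  y <- samples$gout
  rows <- lapply(seq_len(nrow(vars)), function(k) {
    v <- vars$variant_id[k]
    d <- genotypes[gidx, v]
    keep <- complete.cases(cbind(y, d, X))
    if (var(d[keep]) == 0) {
      message("monomorphic variant skipped: ", v)
      return(NULL)
    }
    Xd <- cbind(`(Intercept)` = 1, d = d[keep],
                X[keep, , drop = FALSE])
    fit <- logit_fit(Xd, y[keep])
    firth <- FALSE
    if (!fit$converged || fit$boundary) {
      fit <- firth_logit(Xd, y[keep])
      firth <- TRUE
      se <- fit$se[2L]
    } else {
      mu <- plogis(drop(Xd %*% fit$coefficients))
      info <- crossprod(Xd * sqrt(pmax(mu * (1 - mu), 1e-12)))
      se <- sqrt(diag(solve(info)))[2L]
    }
    z <- fit$coefficients[2L] / se
    data.frame(variant_id = v, target = "gout", position = vars$position[k],
               effect = unname(fit$coefficients[2L]), statistic = unname(z),
               p = 2 * pnorm(-abs(z)), n_used = sum(keep), firth = firth,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("all variants in the window are monomorphic")
  out
}

#' Variants concurrently associated with methylation and gout
#'
#' Intersects a cis-meQTL scan and a disease scan of the same window:
#' variants with meQTL p < `alpha` and disease p < `alpha` (nominal, no
#' within-window multiplicity correction, mirroring a conservative stance
#' toward declaring a CpG genetically independent). Output is ordered by
#' position.
#'
#' @param meqtl_records Records from [scan_meqtl()].
#' @param disease_records Records from [scan_disease()].
#' @param alpha Concurrence threshold (default 0.05).
#' @return Character vector of shared variant ids (possibly empty).
#' @export
find_shared_variants <- function(meqtl_records, disease_records,
                                 alpha = 0.05) {
  if (!setequal(meqtl_records$variant_id, disease_records$variant_id))
    stop("meQTL and disease scans cover different variant sets; ",
         "records must come from the same window")
  m <- merge(meqtl_records[, c("variant_id", "position", "p")],
             disease_records[, c("variant_id", "p")],
             by = "variant_id", suffixes = c("_meqtl", "_gout"))
  shared <- m[m$p_meqtl < alpha & m$p_gout < alpha, ]
  shared <- shared[order(shared$position, shared$variant_id), ]
  shared$variant_id
}

#' Regional table combining both scans
#'
#' @inheritParams find_shared_variants
#' @return Data frame with `variant_id`, `position`, `p_meqtl`, `p_gout`,
#'   `shared_flag`, ordered by position.
#' @export
regional_table <- function(meqtl_records, disease_records, alpha = 0.05) {
  shared <- find_shared_variants(meqtl_records, disease_records, alpha)
  m <- merge(meqtl_records[, c("variant_id", "position", "p")],
             disease_records[, c("variant_id", "p")],
             by = "variant_id", suffixes = c("_meqtl", "_gout"))
  names(m) <- c("variant_id", "position", "p_meqtl", "p_gout")
  m$shared_flag <- m$variant_id %in% shared
  m[order(m$position, m$variant_id), ]
}
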