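# Four-component causal inference test for a (variant L, CpG G, outcome T)
# triple, supporting the chain L -> G -> T. Omnibus p is the maximum of the
# four component p-values, so the chain is declared only when every
# component condition holds:
#   1. T is associated with L                (LRT of L in T ~ L + cov)
#   2. G is associated with L given T       (t-test of L in G ~ L + T + cov)
#   3. T is associated with G given L       (LRT of G in T ~ G + L + cov)
#   4. L is independent of T given G        (equivalence-style: see below)
# Component 4 cannot be a plain significance test (its "good" outcome is a
# null), so it is calibrated against the no-mediation alternative by
# parametric replication: the observed statistic S_obs is the LRT chi-square
# for L in T ~ L + G + cov; B replicate outcomes are generated from a
# logistic model carrying the marginal L->T coefficient on top of the fitted
# G and covariate terms, S* recomputed for each, and
# p4 = (1 + #{S* <= S_obs}) / (B + 1): a small S_obs (no residual L->T
# signal, as mediation predicts) gives a small p4.

#' Causal inference test for one variant-CpG-gout triple
#'
#' @param betas Samples-by-probes beta matrix.
#' @param genotypes Samples-by-variants dosage matrix.
#' @param samples Sample table with the 0/1 `gout` outcome.
#' @param variant_id Variant L.
#' @param probe_id CpG G.
#' @param covariate_set Covariates entering every component.
#' @param B Number of parametric replicates for component 4 (>= 100).
#' @param seed Integer seed; identical seeds give identical results.
#' @return One-row data frame with `p1`..`p4`, `p_omnibus`
#'   (= max of the four), component statistics, `n_used`, `B`, `seed`, and a
#'   `firth` flag set when any binary-outcome component needed a penalized
#'   refit.
#' @export
cit_test <- function(betas, genotypes, samples, variant_id, probe_id,
                     covariate_set = DEFAULT_COVARIATES, B = 500L,
                     seed = 1L) {
  if (B < 100) stop("B must be at least 100")
  if (!variant_id %in% colnames(genotypes))
    stop("variant not in genotype matrix: ", variant_id)
  if (!probe_id %in% colnames(betas))
    stop("probe not in beta matrix: ", probe_id)
  bidx <- match(samples$sample_id, rownames(betas))
  gidx <- match(samples$sample_id, rownames(genotypes))
  if (anyNA(bidx) || anyNA(gidx))
    stop("sample ids must be present in both beta and genotype matrices")
  L <- genotypes[gidx, variant_id]
  G <- betas[bidx, probe_id]
  T_ <- samples$gout
  X <- build_covariate_design(samples, covariate_set)
  keep <- complete.cases(cbind(L, G, T_, X))
  n_used <- sum(keep)
  if (n_used < 50)
    stop(sprintf("only %d complete cases; at least 50 required", n_used))
  L <- L[keep]; G <- G[keep]; T_ <- T_[keep]
  X <- X[keep, , drop = FALSE]
  if (length(unique(T_)) < 2) stop("both outcome classes must be present")
  if (var(L) == 0) stop("dosage is constant for variant ", variant_id)

  X0 <- cbind(`(Intercept)` = 1, X)          # covariates only
  XL <- cbind(X0[, 1, drop = FALSE], L = L, X)
  XG <- cbind(X0[, 1, drop = FALSE], G = G, X)
  XLG <- cbind(X0[, 1, drop = FALSE], L = L, G = G, X)

  firth_used <- FALSE

  # p1: T ~ L + cov, LRT for L
  c1 <- logit_lrt(XL, X0, T_)
  firth_used <- firth_used || c1$firth

  # p2: G ~ L + T + cov, two-sided t for L
  df2 <- data.frame(G = G, L = L, T_ = T_)
  if (ncol(X) > 0) df2 <- cbind(df2, as.data.frame(X))
  cf2 <- summary(lm(G ~ ., data = df2))$coefficients
  stat2 <- cf2["L", "t value"]
  p2 <- cf2["L", "Pr(>|t|)"]

  # shared full model for components 3 and 4
  f_full <- logit_fit(XLG, T_)
  f_red3 <- logit_fit(XL, T_)                # drop G
  f_red4 <- logit_fit(XG, T_)                # drop L
  if (!f_full$converged || f_full$boundary || !f_red3$converged ||
      f_red3$boundary || !f_red4$converged || f_red4$boundary) {
    f_full <- firth_logit(XLG, T_)
    f_red3 <- firth_logit(XL, T_)
    f_red4 <- firth_logit(XG, T_)
    firth_used <- TRUE
  }
  stat3 <- max(0, 2 * (f_full$loglik - f_red3$loglik))
  p3 <- pchisq(stat3, 1, lower.tail = FALSE)
  s_obs <- max(0, 2 * (f_full$loglik - f_red4$loglik))

  # p4: parametric replication under the no-mediation alternative;
  # the marginal T ~ L + cov coefficients were already fit for component 1
  beta_marg_L <- c1$coefficients[2L]
  null_fit <- if (f_red4$firth %||% FALSE) f_red4 else logit_fit(XG, T_)
  lp_null <- drop(XG %*% null_fit$coefficients) + beta_marg_L * L
  pr_null <- plogis(lp_null)
  s_star <- withr::with_seed(seed, {
    U <- matrix(runif(n_used * B), n_used, B)
    vapply(seq_len(B), function(b) {
      Tb <- as.numeric(U[, b] < pr_null)
      if (length(unique(Tb)) < 2) return(0)
      fb <- logit_fit(XLG, Tb)
      rb <- logit_fit(XG, Tb)
      if (!fb$converged || fb$boundary || !rb$converged || rb$boundary) {
        fb <- firth_logit(XLG, Tb)
        rb <- firth_logit(XG, Tb)
      }
      max(0, 2 * (fb$loglik - rb$loglik))
    }, numeric(1))
  })
  p4 <- (1 + sum(s_star <= s_obs)) / (B + 1)

  ps <- c(p1 = c1$p, p2 = p2, p3 = p3, p4 = p4)
  data.frame(variant_id = variant_id, probe_id = probe_id,
             p1 = ps[["p1"]], p2 = ps[["p2"]], p3 = ps[["p3"]],
             p4 = ps[["p4"]], p_omnibus = max(ps),
             stat1 = c1$statistic, stat2 = stat2, stat3 = stat3,
             stat4 = s_obs, n_used = n_used, B = as.integer(B),
             seed = as.integer(seed), firth = firth_used,
             stringsAsFactors = FALSE)
}

#' Causal inference tests for every shared variant of a CpG
#'
#' Runs [cit_test()] once per shared variant in a deterministic order
#' (by position when variant annotation is supplied, otherwise input order),
#' with per-variant seeds `seed + 0, seed + 1, ...` so the batch equals
#' element-wise [cit_test()] calls with those seeds.
#'
#' @inheritParams cit_test
#' @param shared_variants Character vector from [find_shared_variants()].
#' @param variant_annotation Optional variant annotation used for ordering.
#' @return Data frame with one [cit_test()] row per variant (empty for an
#'   empty input, with the same columns).
#' @export
cit_batch <- function(shared_variants, probe_id, betas, genotypes, samples,
                      variant_annotation = NULL,
                      covariate_set = DEFAULT_COVARIATES, B = 500L,
                      seed = 1L) {
  if (length(shared_variants) == 0) {
    out <- cit_result_prototype()
    return(out)
  }
  if (!is.null(variant_annotation)) {
    pos <- variant_annotation$position[match(shared_variants,
                                             variant_annotation$variant_id)]
    shared_variants <- shared_variants[order(pos, shared_variants)]
  }
  res <- lapply(seq_along(shared_variants), function(i)
    cit_test(betas, genotypes, samples, shared_variants[i], probe_id,
             covariate_set = covariate_set, B = B,
             seed = seed + i - 1L))
  do.call(rbind, res)
}

cit_result_prototype <- function() {
  data.frame(variant_id = character(0), probe_id = character(0),
             p1 = numeric(0), p2 = numeric(0), p3 = numeric(0),
             p4 = numeric(0), p_omnibus = numeric(0), stat1 = numeric(0),
             stat2 = numeric(0), stat3 = numeric(0), stat4 = numeric(0),
             n_used = integer(0), B = integer(0), seed = integer(0),
             firth = logical(0), stringsAsFactors = FALSE)
}
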