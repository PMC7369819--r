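test_that("with no covariates the binary-outcome coefficient is the mean difference", {
  withr::with_seed(1, {
    n <- 60
    gout <- rep(c(0, 1), each = n / 2)
    b <- ifelse(gout == 1, 0.55, 0.50) + rnorm(n, 0, 0.01)
    b <- pmin(pmax(b, 0), 1)
    betas <- matrix(b, n, 1, dimnames = list(sprintf("S%02d", 1:n), "cg1"))
    samples <- data.frame(sample_id = rownames(betas), gout = gout)
    r <- fit_cpg_association(betas, samples, "cg1",
                             covariate_set = character(0))
    expect_equal(r$delta_beta, mean(b[gout == 1]) - mean(b[gout == 0]),
                 tolerance = 1e-12)
    # antisymmetry under swapping case/control labels
    samples2 <- samples
    samples2$gout <- 1 - samples2$gout
    r2 <- fit_cpg_association(betas, samples2, "cg1",
                              covariate_set = character(0))
    expect_equal(r2$delta_beta, -r$delta_beta, tolerance = 1e-12)
  })
})

test_that("an orthogonal covariate leaves the estimate unchanged", {
  withr::with_seed(2, {
    n <- 200
    gout <- rep(c(0, 1), each = n / 2)
    b <- 0.5 + 0.03 * gout + rnorm(n, 0, 0.02)
    z_raw <- rnorm(n)
    # orthogonalize z against both the outcome and the methylation
    z <- residuals(lm(z_raw ~ gout + b))
    betas <- matrix(pmin(pmax(b, 0), 1), n, 1,
                    dimnames = list(sprintf("S%03d", 1:n), "cg1"))
    samples <- data.frame(sample_id = rownames(betas), gout = gout, z = z)
    r0 <- fit_cpg_association(betas, samples, "cg1",
                              covariate_set = character(0))
    r1 <- fit_cpg_association(betas, samples, "cg1", covariate_set = "z")
    expect_lt(abs(r1$delta_beta - r0$delta_beta), 1e-10)
  })
})

test_that("degenerate probes and collinear covariates are rejected", {
  n <- 40
  betas <- matrix(0.5, n, 1, dimnames = list(sprintf("S%02d", 1:n), "cg1"))
  samples <- data.frame(sample_id = rownames(betas),
                        gout = rep(c(0, 1), n / 2),
                        a = rnorm(n))
  samples$b <- 2 * samples$a
  expect_error(fit_cpg_association(betas, samples, "cg1",
                                   covariate_set = character(0)),
               "degenerate probe")
  betas[, 1] <- runif(n)
  expect_error(fit_cpg_association(betas, samples, "cg1",
                                   covariate_set = c("a", "b")),
               "collinear")
})

test_that("BH adjustment matches the brute-force oracle", {
  # worked example: four probes at p = .01, .02, .03, .04 all get q = .04
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  withr::with_seed(3, {
    for (i in 1:25) {
      p <- runif(sample(1:200, 1))^sample(1:3, 1)
      expect_lt(max(abs(p.adjust(p, "BH") - bh_oracle(p))), 1e-12)
    }
  })
})

test_that("promoter restriction is enforced and q covers only tested probes", {
  ch <- make_test_cohort(seed = 4, n = 300)
  samples <- with_cell_props(ch)
  res <- promoter_ewas(ch$betas, samples, ch$cpg_annotation)
  promo <- ch$cpg_annotation$probe_id[
    ch$cpg_annotation$genomic_feature %in% c("TSS1500", "TSS200", "5UTR")]
  expect_setequal(res$probe_id, promo)
  expect_equal(sort(res$q), sort(bh_oracle(res$p)), tolerance = 1e-12)
  expect_true(all(res$q >= res$p - 1e-15))
  # a Body-only annotation errors
  anno_body <- ch$cpg_annotation
  anno_body$genomic_feature <- "Body"
  expect_error(promoter_ewas(ch$betas, samples, anno_body), "no promoter")
})

test_that("promoter EWAS is invariant to probe and sample permutation", {
  ch <- make_test_cohort(seed = 5, n = 250)
  samples <- with_cell_props(ch)
  r1 <- promoter_ewas(ch$betas, samples, ch$cpg_annotation)
  withr::with_seed(6, {
    bp <- ch$betas[sample(nrow(ch$betas)), sample(ncol(ch$betas))]
    sp <- samples[sample(nrow(samples)), ]
  })
  r2 <- promoter_ewas(bp, sp, ch$cpg_annotation)
  rownames(r1) <- rownames(r2) <- NULL
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("a strong methylation-trait relation is detected, a constant trait errors", {
  ch <- make_test_cohort(seed = 7, n = 2000)
  samples <- ch$samples
  withr::with_seed(8, {
    samples$bmi <- ch$betas[match(samples$sample_id, rownames(ch$betas)),
                            "cg_sim_t01"] + rnorm(nrow(samples), 0, 0.01)
  })
  res <- trait_specificity(ch$betas, samples, "cg_sim_t01",
                           traits = c("bmi", "hba1c", "total_cholesterol"))
  expect_lt(res$p[res$outcome == "bmi"], 1e-6)
  expect_false(res$gout_specific[1])
  samples$hba1c <- 5.5
  expect_error(trait_specificity(ch$betas, samples, "cg_sim_t01"),
               "degenerate outcome")
  expect_error(trait_specificity(ch$betas, ch$samples, "cg_sim_t01",
                                 traits = "missing_trait"), "missing")
})

test_that("three-group contrasts recover the gouty-inflammation pattern", {
  cfg <- simulation_config(n_samples = 2000, scenarios = "independent",
                           n_null_cpgs = 2, delta_beta_target = 0.08,
                           seed = 9)
  ch <- simulate_cohort(cfg)
  samples <- with_cell_props(ch)
  res <- three_group_contrasts(ch$betas, samples, "cg_sim_t01")
  expect_equal(sort(unique(res$contrast)),
               c("hyper_vs_gout", "normo_vs_hyper"))
  expect_true(res$inflammation_pattern[1])
  expect_lt(res$p[res$contrast == "hyper_vs_gout"], 0.05)
  expect_gt(res$p[res$contrast == "normo_vs_hyper"], 0.05)
  # sign: gout-shifted probe rises from hyperuricemia to gout
  expect_gt(res$difference[res$contrast == "hyper_vs_gout"], 0)
})

test_that("a tiny urate group is skipped with a warning", {
  ch <- make_test_cohort(seed = 10, n = 100, hyper_fraction = 0.02)
  samples <- ch$samples
  expect_warning(res <- three_group_contrasts(ch$betas, samples, "cg_sim_t01"),
                 "below")
  expect_equal(nrow(res), 0)
})

test_that("co-methylation: an identical neighbour has r = 1, independent ones stay low", {
  ch <- make_test_cohort(seed = 11, n = 600)
  betas <- ch$betas
  anno <- ch$cpg_annotation
  # plant a duplicate of the target on the same gene
  twin <- betas[, "cg_sim_t01", drop = FALSE]
  colnames(twin) <- "cg_twin"
  betas <- cbind(betas, twin)
  anno <- rbind(anno, data.frame(probe_id = "cg_twin",
                                 chromosome = anno$chromosome[1],
                                 position = anno$position[1] + 500,
                                 gene = anno$gene[1],
                                 genomic_feature = "TSS1500",
                                 cpg_island = TRUE))
  samples <- ch$samples
  res <- comethylation_neighbors(betas, samples, anno, "cg_sim_t01",
                                 window_bp = 1e6)
  expect_equal(res$r[res$neighbor == "cg_twin"], 1, tolerance = 1e-12)
  expect_true(res$comethylated[res$neighbor == "cg_twin"])
  # independent null probes on other chromosomes are not neighbours at all;
  # check low correlation against an independent same-chromosome probe
  anno2 <- anno
  anno2$chromosome[anno2$probe_id == "cg_sim_n001"] <- anno$chromosome[1]
  anno2$position[anno2$probe_id == "cg_sim_n001"] <- anno$position[1] + 1000
  res2 <- comethylation_neighbors(betas, samples, anno2, "cg_sim_t01",
                                  window_bp = 1e6)
  expect_lt(abs(res2$r[res2$neighbor == "cg_sim_n001"]), 0.15)
  expect_false(res2$comethylated[res2$neighbor == "cg_sim_n001"])
})

test_that("a shared latent factor flags a co-methylated block", {
  withr::with_seed(12, {
    n <- 400
    f <- rnorm(n)
    lam <- 0.95
    block <- sapply(1:3, function(j)
      plogis(0.2 + lam * f + rnorm(n, 0, sqrt(1 - lam^2) * 0.4)))
    colnames(block) <- c("cg_a", "cg_b", "cg_c")
    rownames(block) <- sprintf("S%04d", 1:n)
    anno <- data.frame(probe_id = colnames(block), chromosome = "1",
                       position = c(1000, 2000, 3000), gene = "G1",
                       genomic_feature = "TSS200", cpg_island = TRUE)
    samples <- data.frame(sample_id = rownames(block),
                          gout = rep(c(0, 1), n / 2))
    res <- comethylation_neighbors(block, samples, anno, "cg_a",
                                   window_bp = 1e4,
                                   covariate_set = character(0))
    expect_true(all(res$comethylated))
  })
})
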