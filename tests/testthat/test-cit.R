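test_that("the omnibus p equals the maximum component p and the run is seeded", {
  ch <- make_test_cohort(seed = 14, n = 600, scenarios = "mediation")
  cv <- strsplit(ch$truth$causal_variants[1], ",")[[1]]
  r1 <- cit_test(ch$betas, ch$genotypes, ch$samples, cv, "cg_sim_t01",
                 B = 200, seed = 99)
  r2 <- cit_test(ch$betas, ch$genotypes, ch$samples, cv, "cg_sim_t01",
                 B = 200, seed = 99)
  expect_identical(r1, r2)
  expect_equal(r1$p_omnibus, max(r1$p1, r1$p2, r1$p3, r1$p4))
  expect_true(all(unlist(r1[, c("p1", "p2", "p3", "p4")]) >= 0))
  expect_true(all(unlist(r1[, c("p1", "p2", "p3", "p4")]) <= 1))
  r3 <- cit_test(ch$betas, ch$genotypes, ch$samples, cv, "cg_sim_t01",
                 B = 200, seed = 100)
  expect_false(identical(r1$p4, r3$p4))
})

test_that("guard rails: small B, constant dosage, few complete cases", {
  ch <- make_test_cohort(seed = 15, n = 200, scenarios = "mediation")
  cv <- strsplit(ch$truth$causal_variants[1], ",")[[1]]
  expect_error(cit_test(ch$betas, ch$genotypes, ch$samples, cv,
                        "cg_sim_t01", B = 50), "at least 100")
  geno0 <- ch$genotypes
  geno0[, cv] <- 1
  expect_error(cit_test(ch$betas, geno0, ch$samples, cv, "cg_sim_t01",
                        B = 200), "constant")
  expect_error(cit_test(ch$betas, ch$genotypes, ch$samples[1:30, ], cv,
                        "cg_sim_t01", B = 200), "at least 50")
})

test_that("all four p-values are invariant under allele recoding", {
  ch <- make_test_cohort(seed = 16, n = 800, scenarios = "mediation")
  cv <- strsplit(ch$truth$causal_variants[1], ",")[[1]]
  r1 <- cit_test(ch$betas, ch$genotypes, ch$samples, cv, "cg_sim_t01",
                 B = 150, seed = 7)
  flipped <- 2 - ch$genotypes
  r2 <- cit_test(ch$betas, flipped, ch$samples, cv, "cg_sim_t01",
                 B = 150, seed = 7)
  expect_equal(c(r1$p1, r1$p2, r1$p3, r1$p4),
               c(r2$p1, r2$p2, r2$p3, r2$p4), tolerance = 1e-6)
})

test_that("under a global null the omnibus rejects at most ~5%", {
  rej <- sapply(1:40, function(s) {
    withr::with_seed(1000 + s, {
      n <- 400
      L <- rbinom(n, 2, 0.3)
      G <- runif(n, 0.3, 0.7)
      T_ <- rbinom(n, 1, 0.15)
      betas <- matrix(G, n, 1, dimnames = list(sprintf("S%04d", 1:n), "cgN"))
      geno <- matrix(L, n, 1, dimnames = list(rownames(betas), "rsN"))
      samples <- data.frame(sample_id = rownames(betas), gout = T_)
    })
    r <- cit_test(betas, geno, samples, "rsN", "cgN",
                  covariate_set = character(0), B = 150, seed = s)
    r$p_omnibus < 0.05
  })
  expect_lte(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 40))
})

test_that("a batch equals element-wise tests with the same per-variant seeds", {
  ch <- simulate_cohort(simulation_config(
    n_samples = 600, scenarios = "mediation", n_null_cpgs = 0,
    n_causal_variants = 2, seed = 17))
  cvs <- strsplit(ch$truth$causal_variants[1], ",")[[1]]
  expect_length(cvs, 2)
  batch <- cit_batch(cvs, "cg_sim_t01", ch$betas, ch$genotypes, ch$samples,
                     variant_annotation = ch$variant_annotation,
                     B = 150, seed = 5)
  expect_equal(nrow(batch), 2)
  for (i in seq_along(cvs)) {
    single <- cit_test(ch$betas, ch$genotypes, ch$samples,
                       batch$variant_id[i], "cg_sim_t01", B = 150,
                       seed = 5 + i - 1L)
    expect_equal(batch[i, ], single, ignore_attr = TRUE)
  }
  # empty input gives an empty, well-typed result
  empty <- cit_batch(character(0), "cg_sim_t01", ch$betas, ch$genotypes,
                     ch$samples)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("p_omnibus", "variant_id") %in% names(empty)))
})

test_that("power under mediation increases with sample size", {
  pow <- sapply(c(500, 2000), function(n) {
    mean(sapply(1:12, function(s) {
      ch <- simulate_cohort(simulation_config(
        n_samples = n, scenarios = "mediation", n_null_cpgs = 0,
        meqtl_effect = 0.8, disease_effect_methylation = 8,
        seed = 3000 + s))
      cv <- strsplit(ch$truth$causal_variants[1], ",")[[1]]
      cit_test(ch$betas, ch$genotypes, ch$samples, cv, "cg_sim_t01",
               B = 150, seed = s)$p_omnibus < 0.05
    }))
  })
  expect_gte(pow[2], pow[1])
})
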