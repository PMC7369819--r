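make_qtl_fixture <- function(seed = 1, n = 300) {
  withr::with_seed(seed, {
    d <- rbinom(n, 2, 0.3)
    betas <- matrix(pmin(pmax(0.4 + 0.05 * d, 0), 1), n, 1,
                    dimnames = list(sprintf("S%04d", 1:n), "cgQ"))
    geno <- matrix(d, n, 1, dimnames = list(rownames(betas), "rsQ"))
    samples <- data.frame(sample_id = rownames(betas),
                          gout = rbinom(n, 1, 0.3))
    anno <- data.frame(probe_id = "cgQ", chromosome = "1", position = 5e5,
                       gene = "G", genomic_feature = "TSS200",
                       cpg_island = TRUE)
    vanno <- data.frame(variant_id = "rsQ", chromosome = "1",
                        position = 5e5 + 100, ref = "A", alt = "G")
    list(betas = betas, geno = geno, samples = samples, anno = anno,
         vanno = vanno)
  })
}

test_that("an exact linear dosage relation is recovered with p ~ 0", {
  fx <- make_qtl_fixture()
  win <- cis_window(fx$anno, "cgQ")
  r <- suppressWarnings(  # lm flags the essentially perfect fit
    scan_meqtl(fx$betas, fx$geno, fx$samples, "cgQ", win, fx$vanno,
               covariate_set = character(0)))
  expect_equal(r$effect, 0.05, tolerance = 1e-10)
  expect_lt(r$p, 1e-200)
})

test_that("monomorphic variants are skipped and an all-monomorphic window errors", {
  fx <- make_qtl_fixture()
  fx$geno[, 1] <- 0
  win <- cis_window(fx$anno, "cgQ")
  expect_error(
    suppressMessages(scan_meqtl(fx$betas, fx$geno, fx$samples, "cgQ", win,
                                fx$vanno, covariate_set = character(0))),
    "monomorphic")
})

test_that("meQTL and disease p-values are invariant under allele-label flips", {
  ch <- make_test_cohort(seed = 13, n = 500, scenarios = "mediation")
  samples <- ch$samples
  win <- cis_window(ch$cpg_annotation, "cg_sim_t01")
  r1 <- suppressMessages(scan_meqtl(ch$betas, ch$genotypes, samples,
                                    "cg_sim_t01", win, ch$variant_annotation))
  d1 <- suppressMessages(scan_disease(ch$genotypes, samples, win,
                                      ch$variant_annotation))
  flipped <- 2 - ch$genotypes
  r2 <- suppressMessages(scan_meqtl(ch$betas, flipped, samples, "cg_sim_t01",
                                    win, ch$variant_annotation))
  d2 <- suppressMessages(scan_disease(flipped, samples, win,
                                      ch$variant_annotation))
  expect_equal(r1$p, r2$p, tolerance = 1e-8)
  expect_equal(r1$effect, -r2$effect, tolerance = 1e-8)
  expect_equal(d1$p, d2$p, tolerance = 1e-6)
})

test_that("the causal variant tops its window under mediation", {
  hits <- sapply(1:10, function(s) {
    ch <- simulate_cohort(simulation_config(
      n_samples = 1000, scenarios = "mediation", n_null_cpgs = 0,
      meqtl_effect = 0.8, seed = 100 + s))
    win <- cis_window(ch$cpg_annotation, "cg_sim_t01")
    r <- suppressMessages(scan_meqtl(ch$betas, ch$genotypes, ch$samples,
                                     "cg_sim_t01", win,
                                     ch$variant_annotation))
    r$variant_id[which.min(r$p)] == ch$truth$causal_variants[1]
  })
  expect_gte(mean(hits), 0.9)
})

test_that("perfect separation takes the Firth path with a finite estimate", {
  n <- 40
  d <- rep(c(0, 2), each = n / 2)
  samples <- data.frame(sample_id = sprintf("S%02d", 1:n),
                        gout = rep(c(0, 1), each = n / 2))
  geno <- matrix(d, n, 1, dimnames = list(samples$sample_id, "rsS"))
  vanno <- data.frame(variant_id = "rsS", chromosome = "1", position = 100,
                      ref = "A", alt = "G")
  win <- list(probe_id = "cgX", chromosome = "1", start = 1, end = 1000)
  r <- scan_disease(geno, samples, win, vanno, covariate_set = character(0))
  expect_true(r$firth)
  expect_true(is.finite(r$effect))
  expect_lt(r$p, 0.05)
})

test_that("shared-variant logic is conjunctive, ordered, and monotone in alpha", {
  mk <- function(p_meqtl, p_gout) {
    list(m = data.frame(variant_id = paste0("v", seq_along(p_meqtl)),
                        position = rev(seq_along(p_meqtl)) * 10,
                        p = p_meqtl),
         d = data.frame(variant_id = paste0("v", seq_along(p_gout)),
                        position = rev(seq_along(p_gout)) * 10,
                        p = p_gout))
  }
  fx <- mk(c(0.04, 0.01, 0.5), c(0.2, 0.01, 0.01))
  expect_equal(find_shared_variants(fx$m, fx$d), "v2")
  # one-sided failure: meQTL significant, disease not
  expect_length(find_shared_variants(mk(c(0.04), c(0.2))$m,
                                     mk(c(0.04), c(0.2))$d), 0)
  # alpha = 0 boundary
  expect_length(find_shared_variants(fx$m, fx$d, alpha = 0), 0)
  # monotone nesting in alpha
  s1 <- find_shared_variants(fx$m, fx$d, alpha = 0.02)
  s2 <- find_shared_variants(fx$m, fx$d, alpha = 0.10)
  expect_true(all(s1 %in% s2))
  # deterministic order by position
  fx2 <- mk(c(0.01, 0.01), c(0.01, 0.01))
  expect_equal(find_shared_variants(fx2$m, fx2$d), c("v2", "v1"))
  # mismatched windows error
  fx3 <- mk(c(0.01), c(0.01))
  fx3$d$variant_id <- "other"
  expect_error(find_shared_variants(fx3$m, fx3$d), "same window")
})

test_that("null meQTL p-values are uniform (KS calibration)", {
  ps <- unlist(lapply(1:4, function(s) {
    ch <- simulate_cohort(simulation_config(
      n_samples = 500, scenarios = "null", n_null_cpgs = 0,
      n_decoy_variants = 25, seed = 200 + s))
    # null CpG: decoy variants have no effect on it
    win <- cis_window(ch$cpg_annotation, "cg_sim_t01")
    suppressMessages(scan_meqtl(ch$betas, ch$genotypes, ch$samples,
                                "cg_sim_t01", win,
                                ch$variant_annotation))$p
  }))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
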