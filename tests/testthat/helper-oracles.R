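# Independent oracles and small fixture builders used across the suite.

# Brute-force Benjamini-Hochberg: sorted p * m / rank with a cumulative
# minimum taken from the largest rank, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  i <- order(p)
  q <- p[i] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[i] <- pmin(q, 1)
  out
}

# Grid search over the 2-simplex (w1, w2 >= 0, w1 + w2 <= 1) at a fixed
# step; returns the grid point with the smallest residual norm for y ~ R w.
simplex_grid_oracle <- function(R, y, step = 1e-3) {
  g <- seq(0, 1, by = step)
  grid <- expand.grid(w1 = g, w2 = g)
  grid <- grid[grid$w1 + grid$w2 <= 1 + 1e-12, ]
  G <- crossprod(R)            # 2x2
  h <- drop(crossprod(R, y))
  w <- as.matrix(grid)
  # ||Rw - y||^2 up to the constant ||y||^2
  obj <- w[, 1]^2 * G[1, 1] + w[, 2]^2 * G[2, 2] +
    2 * w[, 1] * w[, 2] * G[1, 2] - 2 * (w[, 1] * h[1] + w[, 2] * h[2])
  unlist(grid[which.min(obj), ])
}

# Small cohort for unit tests (modest n, few null probes).
make_test_cohort <- function(seed = 1, n = 400, scenarios = "independent",
                             ...) {
  simulate_cohort(simulation_config(n_samples = n, scenarios = scenarios,
                                    n_null_cpgs = 5, seed = seed, ...))
}

# Attach deconvolved cell proportions to a cohort's sample table.
with_cell_props <- function(cohort) {
  props <- estimate_cell_proportions(cohort$betas, cohort$panel_reference)
  ct <- setdiff(names(props), c("sample_id", "residual_norm"))
  pm <- props[match(cohort$samples$sample_id, props$sample_id), ct,
              drop = FALSE]
  names(pm) <- paste0("prop_", ct)
  cbind(cohort$samples, pm)
}

# Minimal VCF written to a temp file.
write_test_vcf <- function(records, path = tempfile(fileext = ".vcf"),
                           samples = c("S1", "S2", "S3")) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}
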