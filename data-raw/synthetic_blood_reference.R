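# Generates the packaged synthetic deconvolution reference:
# 6 leukocyte subsets x 300 discriminating probes, fixed seed, written once to
# inst/extdata/synthetic_blood_reference.tsv. Each probe is strongly
# hypomethylated in exactly one subset and methylated elsewhere, which yields a
# well-conditioned reference for constrained projection. The panel is
# synthetic: it mimics the structure (not the probe content) of sorted-cell
# reference panels.
set.seed(20260901)
cell_types <- c("Gran", "CD4T", "CD8T", "Bcell", "Mono", "NK")
n_probes <- 300L
probe_ids <- sprintf("dp%05d", seq_len(n_probes))
R <- matrix(NA_real_, n_probes, length(cell_types),
            dimnames = list(probe_ids, cell_types))
low_in <- rep(seq_along(cell_types), length.out = n_probes)
for (j in seq_len(n_probes)) {
  hi <- runif(length(cell_types), 0.70, 0.95)
  hi[low_in[j]] <- runif(1, 0.05, 0.25)
  R[j, ] <- hi
}
R <- round(R, 4)
df <- data.frame(probe_id = probe_ids, R, check.names = FALSE)
write.table(df, "inst/extdata/synthetic_blood_reference.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
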