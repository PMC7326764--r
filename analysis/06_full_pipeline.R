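#!/usr/bin/env Rscript
# One-call reproduction: the same stages as 01-05 driven by a single
# validated config through run_pipeline(), writing a machine-readable
# summary.json. Re-running this script reproduces the summary byte for
# byte.

library(strokenet)

config <- list(
  seed = 20260925L,
  output_dir = "results/pipeline",
  simulate = list(
    cohort = TRUE, n_case = 507, n_control = 503,
    pathways = list(list(snp = "rs161818", mediator = "systolic_BP",
                         a = 10, b = 0.05, c_prime = 0))
  ),
  simulate_targets = list(m = 100, n_genes = 205, targets_per_gene = 5,
                          modules = list(list(genes = 5, shared = 10))),
  mediation = list(snps = c("rs161818", "rs10887800", "rs4073259"),
                   mediators = c("systolic_BP", "HDL", "Glu"),
                   outcomes = "IS"),
  nsim = 500, k_min = 1, k_max = 2, n_folds = 10, n_perm = 0
)

summary <- run_pipeline(config)
cat("\nsummary.json keys:\n")
cat(paste(" -", names(summary)), sep = "\n")
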