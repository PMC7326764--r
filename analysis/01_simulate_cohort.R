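#!/usr/bin/env Rscript
# Build the synthetic study cohort: 507 cases / 503 controls genotyped at
# the 14 candidate SNPs, with one planted mediation pathway (a dominant
# rs161818 effect on systolic blood pressure that carries the whole
# genotype-stroke association). Writes the cohort tables that the later
# stages read back, so the pipeline runs exactly as it would on real files.

library(strokenet)

seed <- 20260925L
dir.create("results", showWarnings = FALSE)

cohort <- simulate_cohort(
  n_case = 507, n_control = 503,
  pathways = list(list(snp = "rs161818", mediator = "systolic_BP",
                       a = 10,       # +10 mmHg per minor-allele carrier
                       b = 0.05,     # log-odds of stroke per mmHg
                       c_prime = 0)),# no direct path: complete mediation
  seed = seed
)

write_cohort(cohort, "results/genotypes.tsv", "results/phenotypes.csv")

cat("cohort:", nrow(cohort$phenotypes), "subjects (",
    sum(cohort$phenotypes$status == "case"), "cases /",
    sum(cohort$phenotypes$status == "control"), "controls ),",
    length(cohort$genotypes$snp_ids), "SNPs\n")
cat("carrier frequency of rs161818:",
    round(mean(recode(cohort$genotypes, "rs161818", "dominant")$values), 3),
    "\n")
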