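#!/usr/bin/env Rscript
# Single-locus stage: Hardy-Weinberg QC on every SNP, then the SNP versus
# risk-factor association scan (dominant and genotypic codings) and the
# genotype-versus-subtype contrasts. Reads the cohort written by
# 01_simulate_cohort.R; writes per-test tables under results/.

library(strokenet)

cohort <- load_cohort("results/genotypes.tsv", "results/phenotypes.csv")

hwe <- hwe_scan(cohort$genotypes)
write.table(hwe, "results/hwe.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("HWE (all subjects): min p =", format(min(hwe$p_value), digits = 3),
    "at", hwe$snp_id[which.min(hwe$p_value)], "\n")

# case-control ascertainment distorts genotype proportions at an associated
# locus, so the textbook check is equilibrium among controls
hwe_ctrl <- hwe_scan(cohort$genotypes,
                     subset = cohort$phenotypes$status == "control")
write.table(hwe_ctrl, "results/hwe_controls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("HWE (controls only): all SNPs in equilibrium?",
    all(hwe_ctrl$p_value > 0.05), "; min p =",
    format(min(hwe_ctrl$p_value), digits = 3), "\n")

assoc <- assoc_scan_all(cohort$genotypes, cohort$phenotypes)
write.table(assoc, "results/assoc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
top <- assoc[order(assoc$p_value), ][1:5, c("snp_id", "coding", "factor",
                                            "test", "p_value")]
cat("association scan:", nrow(assoc), "tests; top hits:\n")
print(top, row.names = FALSE)

# subtype contrasts for the planted SNP, recessive two-group contrast
rows <- lapply(c("atherothrombosis", "lacunar", "combination"), function(st) {
  subtype_scan(recode(cohort$genotypes, "rs161818", "dominant"),
               cohort$phenotypes$subtype, st)
})
subtypes <- do.call(rbind, rows)
write.table(subtypes, "results/subtype_assoc.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("subtype contrasts written for rs161818\n")
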