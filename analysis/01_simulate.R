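#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs at the default scenario —
# a two-arm HER2-negative platform-trial cohort (106 experimental / 128
# control) with staggered accrual, an expression matrix with embedded
# ligand and receptor-activation signature blocks, and longitudinal HbA1c
# series for the experimental arm. Writes the interchange files that the
# later stages read.

library(ispyengine)

seed <- 20260901L
dir.create("results", showWarnings = FALSE)
cfg <- scenario_config()

pat <- simulate_trial(cfg, seed = seed)
write_patient_table(pat, "results/patients.csv")
cat("patients:", nrow(pat), "(",
    paste(names(table(pat$arm)), table(pat$arm), collapse = ", "), ")\n")
cat("HR+ fraction:", round(mean(pat$hr), 3),
    " MP-Hi2 fraction:", round(mean(pat$mp_class == "Hi2"), 3), "\n")

sim <- simulate_expression(cfg, seed = seed + 1L)
expr_out <- data.frame(gene = rownames(sim$expr), sim$expr,
                       check.names = FALSE)
write.table(expr_out, "results/expression.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
writeLines(sim$ligand_signature$genes, "results/ligand_signature.txt")
write.table(data.frame(gene = names(sim$creighton_signature$signs),
                       sign = unname(sim$creighton_signature$signs)),
            "results/creighton_signature.tsv", sep = "\t",
            row.names = FALSE, col.names = FALSE, quote = FALSE)
cat("expression:", nrow(sim$expr), "genes x", ncol(sim$expr),
    "patients; signature blocks:",
    length(sim$ligand_signature$genes), "ligand /",
    length(sim$creighton_signature$genes), "activation genes\n")

hb <- simulate_hba1c(cfg, seed = seed + 2L)
write.csv(hb, "results/hba1c.csv", row.names = FALSE)
cat("HbA1c: ", length(unique(hb$patient_id)), "patients,",
    nrow(hb), "measurements\n")

manifest <- run_manifest(seed, cfg,
                         inputs = character(0))
write_report(unclass(manifest), "results/01_manifest.json")
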