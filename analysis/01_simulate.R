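#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# Emulates a microsatellite-stratified colorectal cancer cohort: 150 tumors
# over a scaled 22-autosome genome (~2,000 genes), CMS labels, subtype-
# dependent copy-number burden, focal amplifications, tumor-purity-admixed
# dosage-driven expression, a compartment-sorted reference, and survival.
# Writes the exact input formats the downstream stages read, plus truth.

suppressMessages(library(cnacms))

seed <- 1
cohort <- simulate_cohort(sim_config(seed = seed))
compref <- simulate_compartment_reference(cohort)

dir.create("results", showWarnings = FALSE)
write_cohort(cohort, "results/cohort")
write_expression(compref$expr, "results/cohort/compartment_expression.tsv")
writeLines(compref$labels, "results/cohort/compartment_labels.txt")

md <- cohort$metadata
cat("cohort written to results/cohort\n")
cat(sprintf("  samples: %d (%d MSS, %d MSI)\n", nrow(md),
            sum(md$msi == "MSS"), sum(md$msi == "MSI")))
print(table(md$cms, useNA = "ifany"))
cat(sprintf("  injected amplifications: %d (%d high-level)\n",
            nrow(cohort$truth$amps), sum(cohort$truth$amps$additional >= 15)))
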