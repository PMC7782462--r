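#!/usr/bin/env Rscript
# Step 1 — simulate the three-year DH testcross program.
#
# Generates the reference breeding program at desk scale (~600 DH lines
# from 40 small biparental populations per year, 1000 dominant markers,
# three locations with one dropped in the final year, two replicates) and
# writes
# the genotype, pedigree and plot-phenotype tables that every later step
# consumes.

suppressPackageStartupMessages(library(dhgs))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
dir.create("results", showWarnings = FALSE)

cfg <- sim_config("reference", seed = seed)
sim <- simulate_program(cfg)

write_markers(sim$markers, "results/genotypes.tsv")
write_tsv_table(sim$pedigree[c("line_id", "parent1", "parent2", "year", "tester")],
                "results/pedigree.tsv")
write_tsv_table(sim$phenotypes, "results/phenotypes.tsv")
write_tsv_table(sim$sib_counts, "results/sib_counts.tsv")

tab <- table(sim$pedigree$year)
message("Simulated ", nrow(sim$pedigree), " DH lines (",
        paste(names(tab), tab, sep = ": ", collapse = ", "), ")")
message("Across-year sib overlap (lines with a full-sib / half-sib in the other year):")
print(sim$sib_counts)
message("Plot-level within-environment H2 implied by the variance targets: ",
        round(attr(sim$phenotypes, "h2_plot"), 3))
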