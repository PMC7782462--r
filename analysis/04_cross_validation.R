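#!/usr/bin/env Rscript
# Step 4 — fivefold cross-validation, single- vs multi-environment model.
#
# Replicated fivefold CV over DH lines (all of a line's records move
# together between folds).  The single-environment GBLUP (SM) is fitted
# per stratum; the reaction-norm model (MM) adds environment main effects
# and the Hadamard-product G-by-E kernel.  At full scale this scheme uses
# 50 replications; a handful suffices here to show the SM/MM contrast.

suppressPackageStartupMessages(library(dhgs))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

dat <- prepare_validation_data(list(
  markers = read_markers("results/genotypes.tsv"),
  pedigree = read_pedigree("results/pedigree.tsv"),
  phenotypes = read_phenotypes("results/phenotypes.tsv")))

res <- list(
  sm = run_cv5(dat, model = "sm", level = "across", n_reps = 3L, seed = seed,
               chain = chain_settings("quick", seed = seed)),
  mm = run_cv5(dat, model = "mm", level = "across", n_reps = 3L, seed = seed,
               chain = chain_settings("quick", seed = seed + 1L))
)
out <- do.call(rbind, lapply(names(res), function(m)
  cbind(model = m, res[[m]]$replicates)))
write_tsv_table(out, "results/cv_accuracy.tsv")
writeLines(render_report(res), "results/cv_report.txt")
message(paste(render_report(res), collapse = "\n"))
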