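#!/usr/bin/env Rscript
# Step 6 — sibship-partitioned across-year prediction.
#
# Repeats the adjacent-year prediction three ways: with all lines, with
# only the full-/half-sib-related lines shared between the years, and with
# only lines carrying no shared parental line.  Distant year pairs without
# sib overlap are skipped with a notice, as such pairs cannot be evaluated.

suppressPackageStartupMessages(library(dhgs))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

dat <- prepare_validation_data(list(
  markers = read_markers("results/genotypes.tsv"),
  pedigree = read_pedigree("results/pedigree.tsv"),
  phenotypes = read_phenotypes("results/phenotypes.tsv")))

pairs <- list(c("Y1", "Y2"), c("Y2", "Y3"), c("Y1", "Y3"))
rows <- list()
for (pr in pairs) {
  for (m in c("all", "shared_sibs", "no_shared_parents")) {
    res <- withCallingHandlers(
      run_sibship_partition(dat, pr[1], pr[2], mode = m,
                            chain = chain_settings("quick", seed = seed)),
      warning = function(w) { message(conditionMessage(w))
        invokeRestart("muffleWarning") })
    rows[[length(rows) + 1L]] <- data.frame(
      train_year = pr[1], test_year = pr[2], mode = m,
      r = res$mean, skipped = res$skipped)
  }
}
out <- do.call(rbind, rows)
write_tsv_table(out, "results/sibship_accuracy.tsv")
print(out, row.names = FALSE)
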