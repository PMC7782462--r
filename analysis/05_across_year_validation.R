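#!/usr/bin/env Rscript
# Step 5 — independent across-year validation.
#
# Predicts the final year's lines from earlier years' data: one-year
# training, two-year training, two-year training subsampled to the
# one-year size (separating training-set size from environmental
# variation), and two-year training plus 50% of the test year converted
# from testing to training.

suppressPackageStartupMessages(library(dhgs))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

dat <- prepare_validation_data(list(
  markers = read_markers("results/genotypes.tsv"),
  pedigree = read_pedigree("results/pedigree.tsv"),
  phenotypes = read_phenotypes("results/phenotypes.tsv")))
qch <- function(k) chain_settings("quick", seed = seed * 10L + k)
n_y2 <- sum(dat$pedigree$year == "Y2")

res <- list(
  one_year = run_across_year(dat, "Y2", "Y3", chain = qch(1)),
  two_year = run_across_year(dat, c("Y1", "Y2"), "Y3", chain = qch(2)),
  size_adjusted = run_size_adjusted(dat, c("Y1", "Y2"), "Y3",
                                    target_size = n_y2, n_reps = 5L,
                                    seed = seed, chain = qch(3)),
  conversion_50pct = run_partial_conversion(dat, c("Y1", "Y2"), "Y3",
                                            fraction = 0.5, n_reps = 5L,
                                            seed = seed, chain = qch(4))
)
out <- do.call(rbind, lapply(names(res), function(m)
  cbind(scheme = m, res[[m]]$replicates)))
write_tsv_table(out, "results/across_year_accuracy.tsv")
writeLines(render_report(res), "results/across_year_report.txt")
message(paste(render_report(res), collapse = "\n"))
message(sprintf(
  "Training-set design: 1-year r = %.2f, 2-year r = %.2f, size-adjusted 2-year r = %.2f, 2-year + 50%% conversion r = %.2f",
  res$one_year$mean, res$two_year$mean, res$size_adjusted$mean,
  res$conversion_50pct$mean))
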