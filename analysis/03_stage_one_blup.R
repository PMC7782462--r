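#!/usr/bin/env Rscript
# Step 3 — stage-one BLUPs and broad-sense heritability.
#
# Fits the incomplete-block mixed model in every year-location trial
# (replicate fixed, block-in-replicate and line random) and the joint
# across-location model per year (adding the line-by-environment term),
# then reports the two broad-sense heritability statistics.  The resulting
# line BLUPs are the "observed phenotypes" of all validation schemes.

suppressPackageStartupMessages(library(dhgs))

pheno <- read_phenotypes("results/phenotypes.tsv")
bl <- stage_one_blups(pheno)
write_tsv_table(bl$within, "results/blups_within.tsv")
write_tsv_table(bl$across, "results/blups_across.tsv")
write_tsv_table(bl$h2, "results/heritability.tsv")

message("Within-environment H2 by trial:")
print(bl$h2[bl$h2$level == "within", c("unit", "sigma_g2", "sigma_e2", "H2")],
      row.names = FALSE)
message("Across-location H2 by year:")
print(bl$h2[bl$h2$level == "across", ], row.names = FALSE)
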