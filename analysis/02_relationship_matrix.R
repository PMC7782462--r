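#!/usr/bin/env Rscript
# Step 2 — MAF filter and genomic relationship matrix.
#
# Reads the dominant-marker table written by step 1, discards markers with
# minor allele frequency below 0.05 (presence-frequency based, as is the
# only sensible definition for presence/absence tags), standardizes the
# remaining markers and builds G = ZZ'/p.

suppressPackageStartupMessages(library(dhgs))

markers <- read_markers("results/genotypes.tsv")
filtered <- maf_filter(markers, threshold = 0.05)
rep <- attr(filtered, "filter_report")
message("MAF filter: ", rep$n_in, " markers in, ", rep$n_kept, " kept, ",
        rep$n_removed, " removed (threshold ", rep$threshold, ")")

G <- grm(standardize_markers(filtered))
write_grm(G, "results/grm.tsv")
message("G is ", nrow(G$G), " x ", ncol(G$G), " from ", G$p,
        " markers; trace = ", round(sum(diag(G$G)), 2),
        " (expected n - 1 = ", nrow(G$G) - 1, ")")
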