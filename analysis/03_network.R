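#!/usr/bin/env Rscript
# Step 3 — SparCC co-occurrence network on the step-1 community.
#
# Applies the prevalence/abundance prefilter (detected in >= 3 samples,
# overall relative abundance > 1e-4), estimates SparCC correlations,
# attaches one-sided bootstrap p-values (row-wise permutation nulls),
# and keeps significant positive edges (rho > 0.4, p < 0.05).

suppressPackageStartupMessages(library(limnoco))
library(data.table)

ab <- as.matrix(fread("results/true_abundance.tsv"), rownames = "species")

filtered <- sparcc_prefilter(ab, min_samples = 3L,
                             min_overall_abundance = 1e-4)
cat(sprintf("prefilter: %d of %d species retained\n",
            nrow(filtered), nrow(ab)))

rho <- sparcc(filtered)
p <- suppressWarnings(
  sparcc_bootstrap(filtered, rho, n_boot = 100L, seed = 11L))
edges <- build_edges(rho, p, rho_min = 0.4, alpha = 0.05)

fwrite(as.data.table(rho, keep.rownames = "species"),
       "results/sparcc_rho.tsv", sep = "\t")
fwrite(as.data.table(p, keep.rownames = "species"),
       "results/sparcc_pvalues.tsv", sep = "\t")
fwrite(edges, "results/edges.tsv", sep = "\t")

cat(sprintf("network: %d significant positive edges over %d species\n",
            nrow(edges), length(unique(c(edges$source, edges$target)))))
cat(sprintf("edge rho range: %.3f - %.3f\n",
            min(edges$rho), max(edges$rho)))
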