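#!/usr/bin/env Rscript
# Step 1 — generate the reference synthetic community with ground truth.
#
# 220 species (4 planted cohorts of 25 + 120 background) across 200
# samples; cohort 1 is coupled to dissolved oxygen. Writes the genome
# catalog, true abundances, sample metadata, planted cohort labels and
# per-sample sequencing stats under results/, plus a small BedGraph
# demonstration directory for the first few genomes.

suppressPackageStartupMessages(library(limnoco))
library(data.table)

dir.create("results", showWarnings = FALSE)
cfg <- reference_cohort_config(seed = 1L)

cs <- simulate_catalog(cfg)
ab <- simulate_abundances(cs, cfg)
ss <- simulate_sample_stats(ab, cs, cfg)

fwrite(cs$catalog, "results/catalog.tsv", sep = "\t")
fwrite(data.table(id = names(cs$truth$true_genome_sizes),
                  true_genome_size = cs$truth$true_genome_sizes),
       "results/true_genome_sizes.tsv", sep = "\t")
fwrite(as.data.table(ab$abundance, keep.rownames = "species"),
       "results/true_abundance.tsv", sep = "\t")
fwrite(ab$samples, "results/samples.tsv", sep = "\t")
fwrite(data.table(species = names(ab$cohort_labels),
                  cohort = ab$cohort_labels),
       "results/cohort_labels.tsv", sep = "\t")
fwrite(ss$stats, "results/sample_stats.tsv", sep = "\t")

# a tiny BedGraph demo (3 genomes x 2 samples) at the generator default
# 100 bp window, showing the on-disk profile format
cfg_demo <- sim_config(n_species = 3L, n_samples = 2L,
                       genome_length_range = c(5e4, 1e5), seed = 2L)
demo <- simulate_community(cfg_demo, depth_profiles = TRUE)
write_profile_dir(demo$profiles, "results/bedgraph_demo")

cat(sprintf("catalog: %d genomes, %d genera with >= 5 members\n",
            nrow(cs$catalog),
            sum(table(parse_taxonomy(cs$catalog$taxonomy)$genus) >= 5)))
cat(sprintf("abundance: %d x %d, max column-sum deviation %.2e\n",
            nrow(ab$abundance), ncol(ab$abundance),
            max(abs(colSums(ab$abundance) - 1))))
cat(sprintf("planted cohorts: %s (background %d)\n",
            paste(table(ab$cohort_labels[ab$cohort_labels != "background"]),
                  collapse = ", "),
            sum(ab$cohort_labels == "background")))
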