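#!/usr/bin/env Rscript
# Step 6 — cross-cutting statistics and the assembled run report:
# genus-level size variability, size/prevalence regressions, cohort
# comparisons (Kruskal-Wallis + Benjamini-Hochberg letters), and the
# manifest of thresholds and seeds.

suppressPackageStartupMessages(library(limnoco))
library(data.table)

catalog <- as.data.frame(fread("results/catalog.tsv"))     # step-1 community
cohorts_df <- fread("results/cohorts.tsv")                 # step-4 cohorts
est_ab <- as.matrix(fread("results/estimated_abundance.tsv"),
                    rownames = "species")                  # step-2 community

gv <- genus_variability(catalog)
cat(sprintf("genus variability: %d genera with >= 5 species-clusters\n",
            nrow(gv)))
if (nrow(gv) >= 3) {
  fit_cv <- linear_fit(gv$mean_size / 1e6, gv$variance / 1e12)
  cat(sprintf("mean size vs variance: r = %.3f\n", fit_cv$pearson_r))
}

# estimated genome size between the recovered cohorts of that community
lab <- setNames(cohorts_df$cohort, cohorts_df$species)
in_net <- catalog$id %in% names(lab)[lab != "background"]
if (sum(in_net) > 10) {
  kw <- kruskal_wallis_bh(catalog$estimated_size[in_net],
                          lab[catalog$id[in_net]])
  cat(sprintf("size between cohorts: H = %.2f, p = %.3g; letters: %s\n",
              kw$h, kw$p,
              paste(sprintf("%s=%s", names(kw$letters), kw$letters),
                    collapse = " ")))
}

# full report for the depth-profiled community of step 2 (its own
# catalog; prevalence from the TAD-estimated abundances)
cfg_ab <- reference_abundance_config(seed = 1L)
catalog_ab <- simulate_catalog(cfg_ab)$catalog
prev <- prevalence_and_average(est_ab)
tables <- build_report(list(catalog = catalog_ab, prevalence = prev,
                            config = cfg_ab),
                       "results/report")

# cohort report for the step-1 community (true abundances, step-4 labels)
ab_true <- as.matrix(fread("results/true_abundance.tsv"),
                     rownames = "species")
pref <- fread("results/environmental_preference.tsv")
prev_co <- prevalence_and_average(ab_true, detection = ab_true > 1e-4)
tables_co <- build_report(list(catalog = catalog, prevalence = prev_co,
                               cohorts = lab,
                               preferences = as.matrix(pref,
                                                       rownames = "cohort"),
                               config = reference_cohort_config(seed = 1L)),
                          "results/report_cohort")
cat(sprintf("reports written to results/report (%d tables) and results/report_cohort (%d tables)\n",
            length(tables), length(tables_co)))
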