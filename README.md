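# limnoco

Simulation and co-occurrence cohort analysis of freshwater metagenome
communities.

## The problem

Freshwater prokaryotes with streamlined genomes (small, AT-rich,
gene-dense) are frequently the most prevalent and abundant members of
lake microbiomes, yet they often lack complete biosynthetic pathways for
amino acids, nucleotides and vitamins — suggesting they depend on
co-occurring neighbors for the metabolites they cannot make. Testing that
idea from competitive-mapping data requires a chain of quantitative
steps, each easy to get subtly wrong: genome-size estimation and
ANI-based dereplication of a genome catalog, coverage-based relative
abundance, correlation inference on compositional data, community
detection with a proper null model, and pathway-completeness scoring.

`limnoco` implements that chain for ecologists and bioinformaticians
working with genome-resolved metagenomics, together with a
synthetic-community generator with exported ground truth, so that every
stage is testable end to end without any external sequencing data.

## Methods at the core

- **Genome catalog** — estimated genome size = assembly size /
  completeness; strict quality gates (completeness > 50%, contamination
  < 5%; high-quality tier > 90%); quality-sorted greedy dereplication at
  ANI > 95% with the highest-quality genome as cluster representative;
  genus-level size variability (mean, sd, variance, CV = sd/mean × 100
  for genera with ≥ 5 species-clusters).
- **Relative abundance** — TAD80 (truncated average depth: drop the 10%
  highest and lowest positional depths, average the rest) divided by
  genome equivalents GE = total bp / average genome size, with the
  average genome size estimated from single-copy marker hits
  (AGS_m = c_m · total bp / hits_m, median over marker families).
  Prevalence = % of samples with detection.
- **Co-occurrence** — SparCC: from log-ratio variances
  t_ij = Var(log x_i/x_j), solve the basis-variance system under the
  sparsity assumption and set
  ρ_ij = (ω_i + ω_j − t_ij)/(2√(ω_i ω_j)), iteratively excluding the
  strongest pairs; one-sided bootstrap p-values from row-permuted
  matrices; edges require ρ > 0.4 and p < 0.05.
- **Cohorts** — Clauset–Newman–Moore greedy modularity, significance
  against 500 degree-preserving rewired networks (1000 swaps each),
  cohorts = communities with ≥ 6 members; within-cohort degree;
  environmental preference = abundance-weighted mean of z-scored
  parameters (absolute latitude, temperature, oxygen).
- **Metabolic potential** — recursive-descent parser for KEGG module
  DEFINITION strings; completeness = % of satisfied non-optional
  top-level steps; module retention (≥ 1 complete genome and > 0%
  completeness in ≥ 20% of genomes); combined multi-module pathways;
  distinct KOs per Mbp by functional category.

See `vignettes/limnoco-methods.Rmd` for the full model descriptions,
defaults and design decisions.

## Worked example

Simulate a community with two planted cohorts (one coupled to dissolved
oxygen), run the network arm, and score recovery against the generator's
ground truth:

```r
library(limnoco)
cfg <- sim_config(n_species = 60L, n_samples = 80L,
                  cohort_sizes = c(12L, 12L), seed = 7L)
cs  <- simulate_catalog(cfg)
ab  <- simulate_abundances(cs, cfg)

net <- cooccurrence_pipeline(ab$abundance, n_boot = 100L,
                             n_perm = 199L, seed = 7L)
sprintf("modularity Q = %.3f (rewiring p = %g)", net$q, net$q_pvalue)
#> "modularity Q = 0.500 (rewiring p = 0)"
attr(net$cohorts, "sizes")
#> cohort_1 cohort_2
#>       12       12
cohort_recovery_ari(net$cohorts, ab$cohort_labels)
#> 1
round(environmental_preference(ab$abundance, net$cohorts, ab$samples), 2)
#>          oxygen temperature abs_latitude
#> cohort_1   0.76       -0.03         0.13
#> cohort_2  -0.27        0.08        -0.05
```

Both planted cohorts are recovered exactly (adjusted Rand index 1), the
network is far more modular than its rewired nulls (no null Q reached the
observed 0.5), and the oxygen-coupled cohort shows the expected positive
oxygen preference (+0.76 sd above baseline) while the uncoupled cohort
sits near zero on every parameter.

The `analysis/` directory contains the numbered drivers of the full
workflow (`01_simulate.R` … `06_report.R`): generation of the reference
community, depth-profile-based abundance estimation, the SparCC network,
cohort extraction with environmental preferences, metabolic-completeness
scoring on the high-quality tier, and the assembled report tables under
`results/`.

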