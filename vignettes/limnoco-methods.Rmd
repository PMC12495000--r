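---
title: "Methods: simulation and co-occurrence cohort analysis of freshwater communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and co-occurrence cohort analysis of freshwater communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and scientific background

Free-living freshwater prokaryotes with streamlined genomes — small,
AT-rich, gene-dense — are often the most prevalent and abundant members of
lake communities, yet they tend to lack complete biosynthetic pathways for
essential metabolites (amino acids, nucleotides, vitamins). One ecological
reading of this pattern is adaptive gene loss: a function can be lost when
its product is available as a community public good, so streamlined
species are expected to co-occur with partners that retain the pathway.
`limnoco` implements the quantitative machinery needed to study that
question from competitive-mapping data: genome-catalog curation,
depth-based relative abundance, compositional co-occurrence networks,
modularity cohorts with environmental preferences, and KEGG-style module
completeness — all driven by a synthetic-community generator with exported
ground truth so that every stage can be validated end to end without any
sequencing data.

# Pipeline stages and their models

## Genome catalog

Genome size of an incomplete assembly is estimated as
`assembly_size / completeness` with completeness a fraction in (0, 1]
(`estimate_genome_size()`). Quality gating is strict on both sides:
medium-to-high quality means completeness > 50% *and* contamination < 5%;
the high-quality tier used for metabolic scoring raises the completeness
bound to 90% (`filter_quality()`).

Dereplication into species-clusters (`dereplicate()`) uses the
operational species boundary ANI > 95%. The clustering rule is
quality-sorted greedy seeding: genomes are ranked by completeness
(descending), contamination (ascending), assembly size (descending), then
id; each unassigned genome in rank order seeds a cluster and absorbs all
unassigned genomes above the ANI threshold to the seed, which becomes the
representative. We chose greedy seeding over single-linkage components
because single linkage chains clusters through intermediate genomes and
can merge distinct species; the ranking also makes representative
selection ("highest completeness, lowest contamination") fall out of the
seeding order, and the size/id tie-breaks make the partition
deterministic. Genus-level size variability (`genus_variability()`)
summarizes genera with at least five species-clusters by mean, sample
standard deviation (n − 1 denominator throughout the package), variance
(sd²) and CV = sd/mean × 100.

## Relative abundance

The abundance signal of genome *g* in sample *s* is the truncated average
depth: positional depths are sorted, `floor(((1 − f)/2) · L)` positions are
dropped from each tail (f = 0.8 by default, i.e. TAD80, discarding the
10% highest and lowest positions), and the remainder averaged
(`tad()`). Zero-depth positions are part of the distribution — a genome
covered on few positions is pulled towards zero through its central
quantiles, which is the intended behaviour of the statistic. The trim
count uses a floor (no interpolated quantiles) so the value is exactly
reproducible from BedGraph-resolution input, and a half-ulp guard is
added before the floor because `1 - 0.8` is slightly below 0.2 in binary
floating point.

Normalization uses genome equivalents: total sequenced bp divided by the
community's average genome size (`genome_equivalents()`). Average genome
size is estimated from universal single-copy marker hits as
`AGS_m = c_m · total_bp / hits_m` per marker family, aggregated by the
median over families with hits (`estimate_avg_genome_size()`). The
calibration model for the simulator draws
`hits_m ~ Binomial(total_reads, c_m · L_read / AGS_true)` with `c_m` the
marker's effective footprint in bp, which makes the estimator above
exactly consistent ("average genome size inversely proportional to marker
hits"). Relative abundance is `TAD80 / GE` (`relative_abundance()`);
detection defaults to abundance > 0, prevalence is the percentage of
samples with detection, and the average relative abundance is taken over
detected samples only (the all-samples average is available via
`zeros_included = TRUE`; both conventions are recorded in the run
manifest).

## SparCC co-occurrence

Correlations on compositional data are biased (closure forces spurious
negative covariance), so the network stage uses the SparCC estimator
(`sparcc()`): from log-ratio variances `t_ij = Var(log(x_i/x_j))` and the
identity `t_ij = ω_i + ω_j − 2 ρ_ij √(ω_i ω_j)`, the basis variances ω
are obtained under the sparsity assumption by solving the linear system
`M ω = rowSums(T)` with `M = (D − 2) I + J`, and
`ρ_ij = (ω_i + ω_j − t_ij) / (2 √(ω_i ω_j))`, clipped to [−1, 1]. The
most strongly correlated pair above the exclusion threshold (0.1) is then
removed from the system and the solve repeated, up to `D − 4` exclusions,
so that a few strongly coupled pairs cannot distort the basis. Inputs are
relative abundances and are renormalized once per sample; when integer
counts are supplied instead, each of 50 inner iterations draws per-sample
fractions from a Dirichlet posterior (counts + 1) and the element-wise
median is returned. Non-positive basis variances (possible on degenerate
draws) are clamped to machine epsilon with a warning.

Edge significance uses permutation bootstraps (`sparcc_bootstrap()`):
each bootstrap permutes every species' abundances across samples
independently, destroying all between-species association while keeping
marginals, and re-runs the full estimator. The p-value is the raw
one-sided upper-tail proportion of null correlations at least as large as
the observed one — no +1 pseudo-count, so p = 0 is attainable, matching
the convention used for the modularity test below. Child seeds per
bootstrap are derived from the root seed up front, so results do not
depend on evaluation order. Only positive co-occurrences with
ρ > 0.4 (strict) and p < 0.05 (strict) become edges (`build_edges()`);
the upper tail is the natural choice since negative associations are
discarded anyway.

The species prefilter retains those detected in at least 3 samples with
an overall relative abundance above 10⁻⁴; "overall" is read as the mean
across all samples (maximum and sum are selectable via `rule=`).

## Cohorts

The edge list is treated as an unweighted simple graph (edges are already
thresholded; a weighted treatment would double-count the correlation
strength). Communities come from Clauset–Newman–Moore greedy modularity
agglomeration (via igraph), cutting the merge dendrogram at the first
maximum of Q — equivalent to stopping when no merge improves modularity.
Significance (`modularity_significance()`) compares the observed Q with Q
re-computed on degree-preserving rewired null graphs (1000 attempted
double-edge swaps per null, swaps creating loops or multi-edges
rejected; degree preservation is asserted on every permutation). Each
null network is clustered anew — the stricter null, since it lets the
algorithm chase whatever structure rewiring leaves behind — rather than
re-using the observed partition. Communities with at least six members
become cohorts, labeled by descending size; smaller communities are
relabeled background to remove spurious clusters
(`extract_cohorts()`). The degree of connectedness is the node degree on
each cohort's induced subgraph, excluding cross-cohort edges.

Environmental preference (`environmental_preference()`) z-scores each
parameter across samples first (sample sd; missing values dropped
pairwise per parameter, never imputed) and then averages the z-scores
with weights equal to the cohort's summed relative abundance per sample.
Standardizing *before* weighting is what produces the above/below
baseline contrast (a cohort abundant in oxygen-rich samples scores
positive on oxygen); the reverse order would conflate parameter units
with abundance structure. The result is a convex combination of z-scores
and therefore bounded by the observed z range.

## Metabolic potential

KEGG module DEFINITION strings are parsed with a recursive-descent
grammar (`parse_definition()`): space-separated steps, comma
alternatives, `+` complexes, `-` optional components, parentheses for
grouping; precedence minus > plus > comma > space. Completeness
(`module_completeness()`) defaults to step-granularity scoring: 100 × the
fraction of satisfied non-optional top-level steps, where an alternative
is satisfied by any branch, a complex by all non-optional subunits, and a
parenthesized group only when fully complete. Optional components never
reduce completeness and are excluded from denominators; a module with no
non-optional steps is undefined (NA). The fractional mode
(`mode = "fractional"`) propagates partial credit through nested groups
for users who prefer anvi'o-style scoring; the strict default is
documented because completeness comparisons across genomes should not
reward fragments of a nested block. Module retention requires (1) at
least one genome with the complete pathway and (2) completeness > 0% in
at least 20% of genomes (read as non-strict ≥ 20%). Combined multi-module
pathways are scored as the unweighted mean of member completeness
(`combined_pathway_completeness()`; a step-weighted mean is selectable —
the aggregation is not standardized, so both are surfaced). Functional
density is distinct KOs per category divided by estimated size in Mbp
(`kos_per_mbp()`), with zero-KO genomes includable or excludable to match
the paired regression variants used in streamlining analyses.

# The synthetic community generator

The generator (`simulate_community()` and friends) emulates the features
of a competitive-mapping survey that the pipeline is sensitive to:

- **Catalog** — genera of about eight species share a genus-level mean
  log genome size (so ≥ 5-member genera always exist for the variability
  analysis); completeness and contamination are uniform on their
  configured ranges; assembly size is exactly
  `true_length × completeness`, so the size estimator must recover the
  true length identically. GC content rises and coding density falls
  with log size, mirroring streamlining.
- **Abundances** — each planted cohort has a latent per-sample log
  factor; members add `loading ×` the factor plus species noise of sd
  `noise_sd`; background species fluctuate independently with matched
  marginal variance (so planted structure is not detectable from
  variances alone); everything is exponentiated and closed to per-sample
  fractions. One cohort's factor is a monotone logistic function of
  dissolved oxygen (half-range `coupling_strength` on the log scale),
  reproducing an oxygen-preference contrast; other covariates
  (temperature, absolute latitude, depth zone) are sampled independently.
  The log-normal choice for species abundances is a modeling decision:
  real surveys only constrain the distribution loosely (long-tailed, most
  species rare).
- **Depth** — positional depth is Poisson with mean
  `abundance × genome_equivalents` per fixed-size window (default 100 bp;
  a config knob, since TAD is quantile-based and only needs resolution
  fine relative to the 10% trim). Zero-abundance species get explicit
  all-zero profiles so prevalence denominators are unambiguous. BedGraph
  output merges equal-depth runs; the reader inverts the writer exactly.
- **Markers** — hits per marker family are Binomial with probability
  `c_m L_read / AGS_true`, the simplest model consistent with the
  estimator (see above), with known constants `c_m`.
- **KO repertoires** — carriage probability follows a logistic link in
  standardized log true genome size with configurable slope, so mean
  biosynthetic completeness rises with genome size for positive slopes
  and is flat at slope 0. True module completeness is computed with the
  same evaluator the analysis uses.

A fixed seed makes all outputs byte-identical; the stages derive
sub-seeds (`seed + 0 … + 4`) so they can be re-run independently.

What the generator does **not** emulate: read-level sequencing error and
mapping ambiguity, assembly/binning artifacts, phylogenetically realistic
taxonomies, temporal autocorrelation, and genuinely absent species
(lognormal abundances are never exactly zero — detection-driven
prevalence variation below 100% only appears after depth simulation).
Passing recovery tests therefore demonstrates correctness of the
estimators and inference machinery under the stated statistical model,
not robustness to upstream bioinformatic noise.

# Defaults, tunable parameters and numerical choices

| Parameter | Default | Units / meaning |
|---|---|---|
| `central_fraction` | 0.8 | TAD central fraction (TAD80) |
| detection rule | abundance > 0 | configurable via `detection=` mask |
| prefilter | ≥ 3 samples, mean abundance > 1e-4 | network inclusion |
| SparCC `exclusion_threshold` | 0.1 | strongest-pair exclusion |
| SparCC `max_exclusions` | D − 4 | exclusion rounds |
| `n_inner` | 50 | Dirichlet iterations (counts input only) |
| `n_boot` | 500 | bootstrap p-value resolution |
| edge thresholds | ρ > 0.4, p < 0.05 | strict inequalities |
| `min_size` | 6 | cohort membership floor |
| `n_perm` / `rewiring_iters` | 500 / 1000 | modularity null ("1000 rewiring iterations" is read as 1000 attempted swaps per null network) |
| quality gates | > 0.5 / > 0.9 compl., < 0.05 contam. | medium / high tier |
| ANI threshold | 95% | species boundary |
| `window_size` | 100 bp | depth-simulation window |
| `coverage_target` | 10× | mean per-species depth |
| `noise_sd`, `factor_sd`, `loading` | 0.5, 1.5, 1 | log-scale cohort model |

Numerical details worth knowing: the TAD trim count guards the floor with
`sqrt(.Machine$double.eps)`; SparCC correlations are clipped to [−1, 1]
and basis variances clamped positive with a warning; greedy-modularity
ties are resolved by the first maximum along the agglomeration path;
`dereplicate()` breaks ranking ties by assembly size then id; raw
proportions (no pseudo-count) are used for both bootstrap and rewiring
p-values; all sds are sample sds.

# Validation problem sizes

The test suite and `scripts/acceptance.R` validate the package at these
scales, chosen once as representative desk-scale study conditions: TAD
against a brute-force oracle on 1000 random vectors (lengths 10–10⁴);
abundance recovery on 100 species × 50 samples at 10× coverage (Pearson
r ≥ 0.95 against truth, exact recovery in the noiseless variant); SparCC
against an independently coded textbook implementation on 20 × 200 shared
fractions (max deviation < 10⁻⁶); bootstrap-p uniformity for an
independent pair over 200 replicate communities of 8 species × 60 samples
at 100 bootstraps; modularity calibration on 200 Erdős–Rényi graphs
(99 permutations each) plus a planted two-block graph at 500
permutations; end-to-end cohort recovery on 4 × 25 planted species + 120
background × 200 samples over 5 seeds (ARI ≥ 0.8 and top oxygen
preference for the coupled cohort in ≥ 4 of 5), with 100 bootstraps for
edge p-values; and module scoring against a brute-force tree oracle on
500 random definition/KO-set pairs. The two reference configurations use
1000 bp depth windows — ≥ 1000 windows per genome at ≥ 1 Mbp, ample for an
80% truncation — while the generator default stays at 100 bp.

# Known limitations

- SparCC requires strictly positive fractions; estimated abundance
  matrices containing zeros should be analyzed via the counts/Dirichlet
  path or after an explicit pseudo-abundance decision by the caller.
- The basis-variance solve assumes sparsity of true correlations; dense
  correlation structure (most pairs correlated) biases ω and hence ρ.
- Greedy modularity has a known resolution limit; very small true
  communities may be absorbed, which the six-member cohort floor
  partially masks.
- Module scoring treats all KO evidence as binary presence; copy number
  and completeness of the underlying gene calls are upstream concerns.
- The compact letter display uses pairwise rank-sum tests with BH
  adjustment; other post-hoc procedures (e.g. Dunn's test) would give
  slightly different letters and are intentionally out of scope.
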