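#' Simulation configuration for a synthetic freshwater community
#'
#' Bundles every knob of the synthetic-community generator: community and
#' cohort structure, abundance noise, environmental coupling, sequencing
#' depth, and genome-quality ranges. The generator exists so that every
#' downstream stage (abundance estimation, co-occurrence inference, cohort
#' detection, metabolic scoring) can be validated against known ground
#' truth; its defaults describe a mid-size stratified-lake-like survey.
#'
#' @param n_species Number of species-cluster representative genomes.
#' @param n_samples Number of metagenome samples.
#' @param cohort_sizes Integer vector of planted cohort sizes (possibly
#'   empty). Species not assigned to a cohort are independent background.
#' @param loading Multiplier applied to each cohort's latent log-factor in
#'   member log-abundances.
#' @param noise_sd Log-scale standard deviation of species-level noise
#'   around the cohort factor. Must be >= 0.
#' @param factor_sd Log-scale standard deviation of the latent factor of
#'   uncoupled cohorts.
#' @param coupled_cohort Index of the cohort whose latent factor follows a
#'   logistic response to oxygen (0 = none).
#' @param coupling_strength Half-range, on the log scale, of the coupled
#'   cohort's logistic oxygen response.
#' @param background_sd Log-scale sd of background species. Defaults to
#'   `sqrt((loading * factor_sd)^2 + noise_sd^2)` so background marginal
#'   variability matches cohort members and planted structure is not
#'   trivially detectable from variances alone.
#' @param coverage_target Mean per-species sequencing depth (x) per sample.
#' @param genome_length_range True genome length range in bp.
#' @param completeness_range Completeness range, fractions in (0, 1].
#' @param contamination_range Contamination range, fractions in [0, 1).
#' @param window_size Depth-simulation window in bp. Positional depth is
#'   drawn per window; resolution only needs to be fine relative to the
#'   TAD trim fraction.
#' @param read_length Simulated read length in bp.
#' @param marker_constants Named numeric vector of effective single-copy
#'   marker footprints in bp, the known calibration constants of the
#'   average-genome-size estimator.
#' @param seed Integer root seed. A fixed seed makes every generator output
#'   byte-identical across runs.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_species = 100L,
                       n_samples = 50L,
                       cohort_sizes = integer(),
                       loading = 1,
                       noise_sd = 0.5,
                       factor_sd = 1.5,
                       coupled_cohort = 1L,
                       coupling_strength = 1.5,
                       background_sd = NULL,
                       coverage_target = 10,
                       genome_length_range = c(1e6, 6e6),
                       completeness_range = c(0.5, 1),
                       contamination_range = c(0, 0.05),
                       window_size = 100L,
                       read_length = 150L,
                       marker_constants = c(rpoB = 1200, gyrB = 1100,
                                            recA = 900, rplB = 700,
                                            infB = 1000),
                       seed = 1L) {
  .check(n_species >= 1 && n_samples >= 1, "need at least one species and one sample")
  .check(sum(cohort_sizes) <= n_species,
         "sum(cohort_sizes) = %d exceeds n_species = %d", sum(cohort_sizes), n_species)
  .check(noise_sd >= 0, "noise_sd must be >= 0")
  .check(coverage_target > 0, "coverage_target must be > 0")
  .check(diff(genome_length_range) >= 0 && genome_length_range[1] > 0,
         "genome_length_range must be a non-empty positive range")
  .check(completeness_range[1] > 0 && completeness_range[2] <= 1 &&
           diff(completeness_range) >= 0,
         "completeness_range must lie in (0, 1]")
  .check(contamination_range[1] >= 0 && contamination_range[2] < 1 &&
           diff(contamination_range) >= 0,
         "contamination_range must lie in [0, 1)")
  .check(window_size >= 1, "window_size must be >= 1 bp")
  if (is.null(background_sd)) {
    background_sd <- sqrt((loading * factor_sd)^2 + noise_sd^2)
  }
  structure(list(
    n_species = as.integer(n_species), n_samples = as.integer(n_samples),
    cohort_sizes = as.integer(cohort_sizes),
    loading = loading, noise_sd = noise_sd, factor_sd = factor_sd,
    coupled_cohort = as.integer(coupled_cohort),
    coupling_strength = coupling_strength, background_sd = background_sd,
    coverage_target = coverage_target,
    genome_length_range = genome_length_range,
    completeness_range = completeness_range,
    contamination_range = contamination_range,
    window_size = as.integer(window_size),
    read_length = as.integer(read_length),
    marker_constants = marker_constants,
    seed = as.integer(seed)), class = "sim_config")
}

#' Reference configurations used throughout the package
#'
#' `reference_abundance_config()` is the community used to validate the
#' depth-to-relative-abundance chain: 100 species, 50 samples, mean
#' coverage 10x. `reference_cohort_config()` is the community used for
#' end-to-end cohort recovery: 4 planted cohorts of 25 species plus 120
#' background species across 200 samples with log-noise 0.5, cohort 1
#' coupled to oxygen. Both use 1000 bp depth windows (ample resolution for
#' an 80% truncation on >= 1 Mbp genomes while keeping depth matrices
#' small).
#'
#' @param seed Integer root seed.
#' @return A `sim_config`.
#' @export
reference_abundance_config <- function(seed = 1L) {
  sim_config(n_species = 100L, n_samples = 50L, coverage_target = 10,
             window_size = 1000L, seed = seed)
}

#' @rdname reference_abundance_config
#' @export
reference_cohort_config <- function(seed = 1L) {
  sim_config(n_species = 220L, n_samples = 200L,
             cohort_sizes = rep(25L, 4), noise_sd = 0.5,
             window_size = 1000L, seed = seed)
}

#' Simulate a genome catalog
#'
#' Draws a catalog of species-representative genomes with taxonomy-linked
#' true genome sizes, quality metrics, and provenance labels. Genera hold
#' about eight species each (so >= 5-member genera, the size-variability
#' cutoff, always exist) and share a genus-level mean log genome size;
#' GC content and coding density co-vary with size the way streamlined
#' freshwater genomes do (small genomes: low GC, high coding density).
#' Assembly size is `true_length * completeness`, so the genome-size
#' estimator (assembly size / completeness) recovers the true length
#' exactly on synthetic catalogs.
#'
#' @param config A [sim_config()].
#' @return A list with `catalog` (data.frame: `id`, `assembly_size`,
#'   `completeness`, `contamination`, `estimated_size`, `taxonomy`,
#'   `derivation`, `environment`, `gc_content`, `coding_density`) and
#'   `truth` (list with `true_genome_sizes`, named bp vector).
#' @export
simulate_catalog <- function(config) {
  .check(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed)
  n <- config$n_species
  lr <- log(config$genome_length_range)

  n_genera <- max(1L, n %/% 8L)
  genus_mu <- runif(n_genera, lr[1] + 0.1 * diff(lr), lr[2] - 0.1 * diff(lr))
  if (diff(lr) == 0) genus_mu <- rep(lr[1], n_genera)
  genus_of <- sample(rep(seq_len(n_genera), length.out = n))
  true_len <- exp(rnorm(n, genus_mu[genus_of], 0.08))
  true_len <- pmin(pmax(true_len, config$genome_length_range[1]),
                   config$genome_length_range[2])

  completeness <- runif(n, config$completeness_range[1], config$completeness_range[2])
  contamination <- runif(n, config$contamination_range[1], config$contamination_range[2])
  assembly_size <- true_len * completeness

  # size-linked composition: streamlined genomes are AT-rich and gene-dense
  z <- if (diff(lr) > 0) (log(true_len) - lr[1]) / diff(lr) else rep(0.5, n)
  gc <- pmin(pmax(0.32 + 0.28 * z + rnorm(n, 0, 0.02), 0.2), 0.75)
  cd <- pmin(pmax(0.965 - 0.06 * z + rnorm(n, 0, 0.005), 0.8), 0.99)

  n_phyla <- max(1L, ceiling(n_genera / 4))
  phylum_of <- rep(seq_len(n_phyla), length.out = n_genera)
  id <- sprintf("G%04d", seq_len(n))
  taxonomy <- sprintf(
    "d__Bacteria;p__phylum_%02d;c__class_%02d;o__order_%02d;f__family_%02d;g__genus_%02d;s__species_%04d",
    phylum_of[genus_of], phylum_of[genus_of], genus_of, genus_of, genus_of, seq_len(n))
  derivation <- sample(c("MAG", "SAG", "isolate"), n, replace = TRUE,
                       prob = c(0.90, 0.07, 0.03))
  environment <- sample(c("freshwater", "non-freshwater"), n, replace = TRUE,
                        prob = c(0.8, 0.2))

  catalog <- data.frame(
    id = id, assembly_size = assembly_size, completeness = completeness,
    contamination = contamination,
    estimated_size = estimate_genome_size(assembly_size, completeness),
    taxonomy = taxonomy, derivation = derivation, environment = environment,
    gc_content = gc, coding_density = cd, stringsAsFactors = FALSE)
  list(catalog = catalog,
       truth = list(true_genome_sizes = setNames(true_len, id)))
}

#' Simulate cohort-structured compositional abundances
#'
#' Members of each planted cohort share a latent log-scale factor across
#' samples (log-normal for uncoupled cohorts; a logistic function of
#' dissolved oxygen for the coupled cohort), scaled by `loading` and
#' perturbed by species-level Gaussian noise of sd `noise_sd`. Background
#' species fluctuate independently. Raw abundances are exponentiated and
#' closed to per-sample fractions, which is what makes the inference
#' problem compositional.
#'
#' @param catalog_sim Output of [simulate_catalog()].
#' @param config The same [sim_config()].
#' @return A list with `abundance` (species x sample fraction matrix,
#'   columns summing to 1), `samples` (data.frame of per-sample
#'   environmental metadata: `oxygen` mg/L, `temperature` deg C,
#'   `abs_latitude` degrees, `depth_zone`), `cohort_labels` (named
#'   character: `"cohort_<k>"` or `"background"`), and `factors`
#'   (cohort x sample latent log-factors).
#' @export
simulate_abundances <- function(catalog_sim, config) {
  .check(inherits(config, "sim_config"), "config must be a sim_config")
  .check(config$noise_sd >= 0, "noise_sd must be >= 0")
  set.seed(config$seed + 1L)
  n <- config$n_species
  ns <- config$n_samples
  ids <- catalog_sim$catalog$id

  sample_id <- sprintf("S%03d", seq_len(ns))
  oxygen <- runif(ns, 0, 12)
  temperature <- pmin(pmax(rnorm(ns, 12, 6), 0), 30)
  abs_latitude <- runif(ns, 30, 69)
  depth_zone <- ifelse(oxygen + rnorm(ns, 0, 1.5) < 4, "hypolimnion", "epilimnion")
  samples <- data.frame(sample = sample_id, oxygen = oxygen,
                        temperature = temperature, abs_latitude = abs_latitude,
                        depth_zone = depth_zone, stringsAsFactors = FALSE)

  k <- length(config$cohort_sizes)
  labels <- rep("background", n)
  if (k > 0) {
    planted <- sample(n, sum(config$cohort_sizes))
    labels[planted] <- rep(sprintf("cohort_%d", seq_len(k)), config$cohort_sizes)
  }
  names(labels) <- ids

  factors <- matrix(0, nrow = max(k, 0), ncol = ns,
                    dimnames = if (k > 0) list(sprintf("cohort_%d", seq_len(k)), sample_id))
  if (k > 0) {
    for (c in seq_len(k)) {
      if (c == config$coupled_cohort) {
        # monotone logistic response of the cohort factor to oxygen
        factors[c, ] <- config$coupling_strength *
          (2 * plogis((oxygen - 6) / 1.5) - 1)
      } else {
        factors[c, ] <- rnorm(ns, 0, config$factor_sd)
      }
    }
  }

  base_mu <- rnorm(n, 0, 1)          # species-level mean log abundance
  loga <- matrix(base_mu, n, ns)
  for (i in seq_len(n)) {
    if (labels[i] == "background") {
      loga[i, ] <- loga[i, ] + rnorm(ns, 0, config$background_sd)
    } else {
      c <- match(labels[i], rownames(factors))
      loga[i, ] <- loga[i, ] + config$loading * factors[c, ] +
        rnorm(ns, 0, config$noise_sd)
    }
  }
  ab <- exp(loga)
  ab <- sweep(ab, 2, colSums(ab), "/")
  dimnames(ab) <- list(ids, sample_id)
  list(abundance = ab, samples = samples, cohort_labels = labels,
       factors = factors)
}

#' Simulate per-sample sequencing totals and marker-gene hits
#'
#' Fixes the sample-level quantities that relative-abundance estimation
#' needs: genome equivalents are set to `coverage_target * n_species`
#' (so the community-mean per-species coverage equals the target), the
#' true average genome size is the abundance-weighted mean of true genome
#' lengths, total bp is their product, and single-copy-marker hits are
#' drawn as `Binomial(total_reads, c_m * read_length / AGS_true)` where
#' `c_m` is the marker's known effective footprint in bp. Under this model
#' the estimator `c_m * total_bp / hits_m` is consistent for the true
#' average genome size.
#'
#' @param abund_sim Output of [simulate_abundances()].
#' @param catalog_sim Output of [simulate_catalog()].
#' @param config The same [sim_config()].
#' @return A list with `stats` (data.frame: `sample`, `total_reads`,
#'   `total_bp`, one `hits_<marker>` column per marker) and `truth`
#'   (list with `avg_genome_size` and `genome_equivalents`, per sample).
#' @export
simulate_sample_stats <- function(abund_sim, catalog_sim, config) {
  set.seed(config$seed + 2L)
  ab <- abund_sim$abundance
  sizes <- catalog_sim$truth$true_genome_sizes[rownames(ab)]
  ags_true <- as.numeric(crossprod(ab, sizes))        # per-sample weighted mean
  ge_true <- rep(config$coverage_target * config$n_species, ncol(ab))
  total_bp <- ge_true * ags_true
  total_reads <- round(total_bp / config$read_length)

  hits <- sapply(config$marker_constants, function(cm) {
    p <- pmin(cm * config$read_length / ags_true, 1)
    rbinom(length(total_reads), size = as.integer(total_reads), prob = p)
  })
  hits <- matrix(hits, nrow = ncol(ab),
                 dimnames = list(NULL, paste0("hits_", names(config$marker_constants))))
  stats <- data.frame(sample = colnames(ab), total_reads = total_reads,
                      total_bp = total_bp, stringsAsFactors = FALSE)
  stats <- cbind(stats, as.data.frame(hits))
  list(stats = stats,
       truth = list(avg_genome_size = setNames(ags_true, colnames(ab)),
                    genome_equivalents = setNames(ge_true, colnames(ab))))
}

#' Simulate windowed depth profiles
#'
#' For genome g in sample s the expected coverage is
#' `abundance[g, s] * genome_equivalents[s]`; positional depth is drawn
#' per `window_size` bp window as Poisson with that mean (or set to the
#' deterministic expectation when `stochastic = FALSE`, the noiseless
#' variant under which relative abundance is recovered exactly). Species
#' with zero abundance get an explicit all-zero profile so detection and
#' prevalence denominators are unambiguous.
#'
#' @param abund_sim Output of [simulate_abundances()].
#' @param catalog_sim Output of [simulate_catalog()].
#' @param config The same [sim_config()].
#' @param sample_stats Output of [simulate_sample_stats()]; generated on
#'   the fly when `NULL`.
#' @param stochastic Draw Poisson depths (`TRUE`, default) or use the
#'   deterministic expected coverage.
#' @return A list with `profiles` (list over samples of lists over genomes
#'   of per-window depth vectors), `window`, `n_windows` (named per
#'   genome), `sample_stats`, and the generating `config`.
#' @export
simulate_depth_profiles <- function(abund_sim, catalog_sim, config,
                                    sample_stats = NULL, stochastic = TRUE) {
  .check(config$coverage_target > 0, "coverage_target must be > 0")
  if (is.null(sample_stats)) {
    sample_stats <- simulate_sample_stats(abund_sim, catalog_sim, config)
  }
  set.seed(config$seed + 3L)
  ab <- abund_sim$abundance
  ge <- sample_stats$truth$genome_equivalents
  sizes <- catalog_sim$truth$true_genome_sizes[rownames(ab)]
  n_win <- setNames(as.integer(ceiling(sizes / config$window_size)), names(sizes))

  profiles <- lapply(colnames(ab), function(s) {
    lam <- ab[, s] * ge[s]
    ps <- lapply(rownames(ab), function(g) {
      if (stochastic) rpois(n_win[g], lam[g]) else rep(lam[g], n_win[g])
    })
    names(ps) <- rownames(ab)
    ps
  })
  names(profiles) <- colnames(ab)
  list(profiles = profiles, window = config$window_size, n_windows = n_win,
       sample_stats = sample_stats, config = config)
}

#' Simulate a genome x KO presence table with size-coupled repertoires
#'
#' The probability that a genome carries a KO follows a logistic link in
#' the standardized log true genome size, `plogis(alpha_k + slope * z_g)`,
#' so larger genomes carry more complete biosynthetic repertoires when
#' `slope > 0` and carriage is size-independent at `slope = 0`. True
#' module completeness is scored with the same evaluator the analysis
#' stage uses ([module_completeness()]).
#'
#' @param catalog_sim Output of [simulate_catalog()].
#' @param modules Module table as returned by [synthetic_modules()]
#'   (columns `module_id`, `category`, `definition`).
#' @param config The [sim_config()].
#' @param slope Logistic slope of KO carriage on standardized log size.
#' @return A list with `ko_table` (logical genome x KO matrix) and
#'   `completeness_true` (genome x module matrix, percent).
#' @export
simulate_ko_table <- function(catalog_sim, modules, config, slope = 1.5) {
  .check(is.data.frame(modules) && nrow(modules) > 0, "empty module list")
  set.seed(config$seed + 4L)
  defs <- lapply(modules$definition, parse_definition)
  kos <- sort(unique(unlist(lapply(defs, definition_kos))))
  sizes <- catalog_sim$truth$true_genome_sizes
  z <- as.numeric(scale(log(sizes)))
  if (any(!is.finite(z))) z <- rep(0, length(sizes))

  alpha <- runif(length(kos), -1.5, 1.5)
  p <- plogis(outer(z, alpha, function(zi, ak) ak + slope * zi))
  carry <- matrix(rbinom(length(p), 1, p) == 1, nrow = length(sizes),
                  dimnames = list(names(sizes), kos))

  comp <- t(apply(carry, 1, function(row) {
    held <- kos[row]
    vapply(defs, module_completeness, numeric(1), kos = held)
  }))
  colnames(comp) <- modules$module_id
  list(ko_table = carry, completeness_true = comp)
}

#' Generate a synthetic KEGG-style module table
#'
#' Builds random, well-formed DEFINITION strings over a synthetic KO
#' universe: space-separated steps, comma alternatives, `+` complexes with
#' occasional `-` optional subunits, and parenthesized subgroups. Stands
#' in for the curated amino acid / nucleotide / vitamin biosynthesis
#' module sets when no KEGG flat file is available; module ids carry a
#' `SYN` prefix to mark them as synthetic.
#'
#' @param n_modules Number of modules.
#' @param n_kos Size of the KO universe to draw leaves from.
#' @param seed Integer seed.
#' @param categories Categories cycled over the modules.
#' @return data.frame with `module_id`, `category`, `definition`.
#' @export
synthetic_modules <- function(n_modules = 40L, n_kos = 200L, seed = 1L,
                              categories = c("amino acid", "nucleotide",
                                             "vitamin", "other")) {
  .check(n_modules >= 1 && n_kos >= 5, "need >= 1 module and >= 5 KOs")
  set.seed(seed)
  universe <- sprintf("K%05d", seq_len(n_kos))
  data.frame(
    module_id = sprintf("SYN%05d", seq_len(n_modules)),
    category = rep(categories, length.out = n_modules),
    definition = vapply(seq_len(n_modules), function(i)
      random_definition(universe), character(1)),
    stringsAsFactors = FALSE)
}

#' Random well-formed module DEFINITION string
#'
#' @param universe Character vector of KO ids to draw from.
#' @param max_depth Maximum nesting depth of parenthesized groups.
#' @return A single definition string.
#' @export
random_definition <- function(universe, max_depth = 2L) {
  step <- function(depth) {
    pick <- function(k) sample(universe, k)
    r <- runif(1)
    if (depth < max_depth && r < 0.15) {
      paste0("(", expr(depth + 1L), ")")
    } else if (r < 0.40) {                       # alternative branches
      paste(pick(sample(2:3, 1)), collapse = ",")
    } else if (r < 0.60) {                       # complex, maybe optional part
      parts <- pick(sample(2:3, 1))
      seps <- sample(c("+", "-"), length(parts) - 1, replace = TRUE,
                     prob = c(0.8, 0.2))
      paste0(parts[1], paste0(seps, parts[-1], collapse = ""))
    } else {
      pick(1)
    }
  }
  expr <- function(depth) {
    n_steps <- sample(2:5, 1)
    paste(vapply(seq_len(n_steps), function(i) step(depth), character(1)),
          collapse = " ")
  }
  expr(0L)
}

#' Run the full generator and write a ground-truth run directory
#'
#' Convenience wrapper chaining catalog, abundances, sample stats, depth
#' profiles, and KO tables, returning everything downstream stages and
#' recovery tests need (including the exported ground truth) in one list.
#'
#' @param config A [sim_config()].
#' @param modules Optional module table; defaults to [synthetic_modules()]
#'   seeded from the config.
#' @param depth_profiles Simulate windowed depth profiles (may be skipped
#'   when only abundances are analyzed).
#' @param stochastic Passed to [simulate_depth_profiles()].
#' @param ko_slope Passed to [simulate_ko_table()].
#' @return A list with elements `catalog`, `abundance`, `samples`,
#'   `cohort_labels`, `factors`, `sample_stats`, `profiles` (or NULL),
#'   `ko`, `modules`, `truth`, `config`.
#' @export
simulate_community <- function(config, modules = NULL, depth_profiles = TRUE,
                               stochastic = TRUE, ko_slope = 1.5) {
  cat_sim <- simulate_catalog(config)
  ab_sim <- simulate_abundances(cat_sim, config)
  ss <- simulate_sample_stats(ab_sim, cat_sim, config)
  prof <- if (depth_profiles) {
    simulate_depth_profiles(ab_sim, cat_sim, config, sample_stats = ss,
                            stochastic = stochastic)
  }
  if (is.null(modules)) modules <- synthetic_modules(seed = config$seed)
  ko <- simulate_ko_table(cat_sim, modules, config, slope = ko_slope)
  list(catalog = cat_sim$catalog, abundance = ab_sim$abundance,
       samples = ab_sim$samples, cohort_labels = ab_sim$cohort_labels,
       factors = ab_sim$factors, sample_stats = ss$stats, profiles = prof,
       ko = ko, modules = modules,
       truth = list(true_abundance = ab_sim$abundance,
                    cohort_labels = ab_sim$cohort_labels,
                    true_genome_sizes = cat_sim$truth$true_genome_sizes,
                    avg_genome_size = ss$truth$avg_genome_size,
                    genome_equivalents = ss$truth$genome_equivalents,
                    module_completeness_true = ko$completeness_true),
       config = config)
}
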