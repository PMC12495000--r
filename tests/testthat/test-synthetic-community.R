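test_that("catalog simulation honours completeness arithmetic and determinism", {
  cfg <- sim_config(n_species = 200L, n_samples = 5L, seed = 7L)
  sim1 <- simulate_catalog(cfg)
  sim2 <- simulate_catalog(cfg)
  expect_identical(sim1, sim2)

  # assembly size = true length x completeness, so the estimator inverts it
  expect_equal(sim1$catalog$assembly_size,
               unname(sim1$truth$true_genome_sizes) * sim1$catalog$completeness)
  expect_equal(unname(sim1$catalog$estimated_size),
               unname(sim1$truth$true_genome_sizes))

  # degenerate completeness range pins assembly size exactly
  cfg08 <- sim_config(n_species = 20L, n_samples = 2L,
                      completeness_range = c(0.8, 0.8),
                      genome_length_range = c(2e6, 2e6), seed = 1L)
  s08 <- simulate_catalog(cfg08)
  expect_equal(s08$catalog$assembly_size, rep(1.6e6, 20))

  # full completeness: assembly equals true length
  cfg1 <- sim_config(n_species = 10L, n_samples = 2L,
                     completeness_range = c(1, 1), seed = 2L)
  s1 <- simulate_catalog(cfg1)
  expect_equal(s1$catalog$assembly_size,
               unname(s1$truth$true_genome_sizes))

  # genera with >= 5 members exist
  genus <- parse_taxonomy(sim1$catalog$taxonomy)$genus
  expect_true(any(table(genus) >= 5))
})

test_that("invalid generator configurations are rejected", {
  expect_error(sim_config(noise_sd = -0.1), "noise_sd")
  expect_error(sim_config(coverage_target = 0), "coverage_target")
  expect_error(sim_config(completeness_range = c(0, 0.5)), "completeness")
  expect_error(sim_config(n_species = 10, cohort_sizes = c(6, 6)),
               "cohort_sizes")
})

test_that("abundance columns close to one and cohort structure is planted", {
  cfg <- sim_config(n_species = 60L, n_samples = 40L,
                    cohort_sizes = c(10L, 10L), seed = 3L)
  cs <- simulate_catalog(cfg)
  ab <- simulate_abundances(cs, cfg)
  expect_lt(max(abs(colSums(ab$abundance) - 1)), 1e-9)
  expect_setequal(names(ab$cohort_labels), cs$catalog$id)
  expect_equal(sum(ab$cohort_labels == "cohort_1"), 10)

  # noiseless limit: within-cohort log-abundance correlation is exactly 1
  cfg0 <- sim_config(n_species = 30L, n_samples = 20L,
                     cohort_sizes = c(8L), loading = 1, noise_sd = 0,
                     seed = 4L)
  ab0 <- simulate_abundances(simulate_catalog(cfg0), cfg0)
  members <- names(ab0$cohort_labels)[ab0$cohort_labels == "cohort_1"]
  cc <- cor(t(log(ab0$abundance[members, ])))
  expect_equal(max(abs(cc[upper.tri(cc)] - 1)), 0, tolerance = 1e-12)
})

test_that("background species are uncorrelated at large sample size", {
  cfg <- sim_config(n_species = 40L, n_samples = 500L, seed = 11L)
  ab <- simulate_abundances(simulate_catalog(cfg), cfg)
  r <- cor(log(ab$abundance[1, ]), log(ab$abundance[2, ]))
  expect_lt(abs(r), 0.15)
})

test_that("planted signal strengthens with loading and weakens with noise", {
  for (seed in 1:3) {
    base <- function(loading, noise_sd) {
      cfg <- sim_config(n_species = 40L, n_samples = 60L,
                        cohort_sizes = c(10L, 10L), loading = loading,
                        noise_sd = noise_sd, seed = seed)
      ab <- simulate_abundances(simulate_catalog(cfg), cfg)
      mean_within_cohort_cor(ab$abundance, ab$cohort_labels)
    }
    expect_gte(base(1, 0.2), base(1, 0.8))
    expect_gte(base(1.5, 0.5), base(0.5, 0.5))
  }
})

test_that("depth profiles follow the expected coverage and zero case", {
  cfg <- sim_config(n_species = 5L, n_samples = 3L, coverage_target = 10,
                    genome_length_range = c(1e5, 1e5), window_size = 100L,
                    seed = 5L)
  cs <- simulate_catalog(cfg)
  ab <- simulate_abundances(cs, cfg)
  ss <- simulate_sample_stats(ab, cs, cfg)
  prof <- simulate_depth_profiles(ab, cs, cfg, sample_stats = ss)

  # mean positional depth tracks expected coverage within 2% at 1e5 bp
  ge <- ss$truth$genome_equivalents
  for (s in names(prof$profiles)) {
    for (g in names(prof$profiles[[s]])) {
      lam <- ab$abundance[g, s] * ge[s]
      if (lam >= 5) {
        expect_lt(abs(mean(prof$profiles[[s]][[g]]) - lam) / lam, 0.02)
      }
    }
  }

  # zero abundance: all-zero profile written as one zero interval
  ab0 <- ab
  ab0$abundance["G0001", ] <- 0
  prof0 <- simulate_depth_profiles(ab0, cs, cfg, sample_stats = ss)
  v <- prof0$profiles[[1]][["G0001"]]
  expect_true(all(v == 0))
  f <- tempfile(fileext = ".bedGraph")
  write_bedgraph(v, f, seqname = "G0001", window = 100L)
  expect_equal(nrow(data.table::fread(f)), 1L)
})

test_that("BedGraph round trip reproduces the depth vector exactly", {
  set.seed(8)
  for (len in c(1L, 17L, 400L)) {
    v <- rpois(len, 3)
    f <- tempfile(fileext = ".bedGraph")
    write_bedgraph(v, f, seqname = "g", window = 100L,
                   genome_length = len * 100L - 37L)
    back <- read_bedgraph(f, window = 100L)
    expect_equal(as.numeric(back), as.numeric(v), ignore_attr = TRUE)
    expect_equal(attr(back, "seqname"), "g")
  }
})

test_that("marker-hit model supports average-genome-size recovery", {
  cfg <- sim_config(n_species = 30L, n_samples = 8L, coverage_target = 50,
                    seed = 6L)
  cs <- simulate_catalog(cfg)
  ab <- simulate_abundances(cs, cfg)
  ss <- simulate_sample_stats(ab, cs, cfg)
  expect_gt(min(ss$stats$total_reads), 1e6)
  hit_cols <- grep("^hits_", names(ss$stats), value = TRUE)
  for (i in seq_len(nrow(ss$stats))) {
    est <- estimate_avg_genome_size(
      ss$stats$total_bp[i],
      setNames(as.numeric(ss$stats[i, hit_cols]),
               sub("^hits_", "", hit_cols)),
      cfg$marker_constants)
    expect_lt(abs(est - ss$truth$avg_genome_size[i]) /
                ss$truth$avg_genome_size[i], 0.05)
  }
})

test_that("KO carriage couples to genome size through the logistic slope", {
  cfg <- sim_config(n_species = 300L, n_samples = 2L, seed = 9L)
  cs <- simulate_catalog(cfg)
  mods <- synthetic_modules(n_modules = 25L, n_kos = 120L, seed = 2L)

  ko_pos <- simulate_ko_table(cs, mods, cfg, slope = 2.5)
  mean_comp <- rowMeans(ko_pos$completeness_true, na.rm = TRUE)
  r_pos <- cor(cs$truth$true_genome_sizes, mean_comp)
  expect_gt(r_pos, 0.5)

  ko_null <- simulate_ko_table(cs, mods, cfg, slope = 0)
  r_null <- cor(cs$truth$true_genome_sizes,
                rowMeans(ko_null$completeness_true, na.rm = TRUE))
  expect_lt(abs(r_null), 0.2)

  # saturation: a genome holding every KO completes every defined module
  all_kos <- colnames(ko_pos$ko_table)
  comp_all <- vapply(mods$definition, module_completeness, numeric(1),
                     kos = all_kos)
  expect_true(all(is.na(comp_all) | comp_all == 100))

  expect_error(simulate_ko_table(cs, mods[0, ], cfg), "empty module")
})

test_that("the full generator is reproducible at a fixed seed", {
  cfg <- sim_config(n_species = 20L, n_samples = 10L,
                    cohort_sizes = c(6L), genome_length_range = c(2e5, 4e5),
                    window_size = 1000L, seed = 13L)
  s1 <- simulate_community(cfg)
  s2 <- simulate_community(cfg)
  expect_identical(s1$abundance, s2$abundance)
  expect_identical(s1$profiles$profiles, s2$profiles$profiles)
  expect_identical(s1$ko, s2$ko)
  # ground truth is sufficient to score recovery: every species labelled
  expect_setequal(names(s1$truth$cohort_labels), s1$catalog$id)
})
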