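test_that("DEFINITION parsing follows the operator precedence", {
  d1 <- parse_definition("K1 K2 K3")
  expect_equal(d1$kind, "seq")
  expect_equal(length(d1$children), 3)
  expect_true(all(vapply(d1$children, function(n) n$kind, character(1)) == "ko"))

  d2 <- parse_definition("K1,K2 K3")
  expect_equal(length(d2$children), 2)        # two steps
  expect_equal(d2$children[[1]]$kind, "alt")  # first is an alternative

  d3 <- parse_definition("K1+K2-K3,K4")
  expect_equal(d3$children[[1]]$kind, "alt")
  cpx <- d3$children[[1]]$children[[1]]
  expect_equal(cpx$kind, "complex")
  expect_true(cpx$children[[3]]$optional)

  d4 <- parse_definition("(K1 K2)+K3")
  expect_equal(d4$children[[1]]$kind, "complex")
  expect_equal(d4$children[[1]]$children[[1]]$kind, "seq")

  expect_error(parse_definition("K1 (K2"), "unbalanced")
  expect_error(parse_definition("K1+"), "position")
  expect_error(parse_definition("K1,,K2"), "position")
  expect_error(parse_definition(""), "non-empty")
})

test_that("parse-serialize-parse is a fixpoint on random definitions", {
  set.seed(91)
  universe <- sprintf("K%05d", 1:60)
  for (i in 1:200) {
    s <- random_definition(universe)
    d <- parse_definition(s)
    s2 <- format_definition(d)
    d2 <- parse_definition(s2)
    expect_identical(unclass(d), unclass(d2))
    expect_identical(s2, format_definition(d2))
  }
})

test_that("module completeness scores top-level steps with recursion", {
  expect_equal(module_completeness("K1 K2 K3", c("K1", "K2")), 200 / 3)
  expect_equal(module_completeness("K1,K2 K3", "K2"), 50)
  expect_equal(module_completeness("K1+K2 K3", c("K1", "K3")), 50)
  expect_equal(module_completeness("K1+K2 K3", c("K1", "K2", "K3")), 100)
  # optional subunits never reduce completeness
  expect_equal(module_completeness("K1-K2", "K1"), 100)
  # a leading-minus step is excluded from the denominator
  expect_equal(module_completeness("-K1 K2", "K2"), 100)
  expect_equal(module_completeness("-K1 K2", character(0)), 0)
  # all-optional module is undefined
  expect_true(is.na(module_completeness("-K1 -K2", "K1")))
  # nested group is all-or-nothing in strict mode
  expect_equal(module_completeness("(K1 K2) K3", c("K1", "K3")), 50)
  expect_equal(module_completeness("(K1 K2) K3", c("K1", "K2", "K3")), 100)
  # fractional mode gives nested partial credit
  expect_equal(module_completeness("(K1 K2) K3", c("K1", "K3"),
                                   mode = "fractional"), 75)
})

test_that("completeness agrees with a brute-force tree oracle", {
  set.seed(92)
  universe <- sprintf("K%05d", 1:40)
  for (i in 1:200) {
    tree <- rand_module_tree(universe)
    s <- render_module_tree(tree)
    kos <- sample(universe, sample(0:25, 1))
    expect_equal(module_completeness(parse_definition(s), kos),
                 oracle_tree_completeness(tree, kos), info = s)
  }
})

test_that("completeness is monotone under KO-set growth", {
  set.seed(93)
  universe <- sprintf("K%05d", 1:30)
  for (i in 1:40) {
    s <- random_definition(universe)
    d <- parse_definition(s)
    kos <- sample(universe, 5)
    prev <- module_completeness(d, kos)
    for (add in sample(setdiff(universe, kos), 10)) {
      kos <- c(kos, add)
      cur <- module_completeness(d, kos)
      if (!is.na(prev)) expect_gte(cur, prev)
      prev <- cur
    }
  }
  # limits: full universe completes everything; empty set scores zero
  d <- parse_definition("K1,K2 K3+K4 (K5 K6)")
  expect_equal(module_completeness(d, sprintf("K%d", 1:6)), 100)
  expect_equal(module_completeness(d, character(0)), 0)
})

test_that("module retention requires a complete genome and 20% positive", {
  mk <- function(vals) matrix(vals, ncol = 1,
                              dimnames = list(NULL, "M1"))
  # 10 genomes: one complete, three positive -> retained (30% >= 20%)
  expect_equal(filter_modules(mk(c(100, 40, 10, rep(0, 7)))), "M1")
  # max completeness 95: fails criterion 1
  expect_equal(length(filter_modules(mk(c(95, 95, 50, rep(10, 7))))), 0)
  # 20 genomes with one complete but only 15% positive: fails criterion 2
  expect_equal(length(filter_modules(mk(c(100, 50, 50, rep(0, 17))))), 0)

  # idempotent and order-independent; matches an exhaustive check
  set.seed(94)
  m <- matrix(sample(c(0, 25, 50, 100), 200, replace = TRUE,
                     prob = c(0.5, 0.2, 0.2, 0.1)), 20, 10,
              dimnames = list(NULL, sprintf("M%02d", 1:10)))
  kept <- filter_modules(m)
  manual <- colnames(m)[apply(m, 2, function(x)
    any(x == 100) && mean(x > 0) >= 0.2)]
  expect_setequal(kept, manual)
  expect_setequal(filter_modules(m[, rev(colnames(m))]), kept)
  expect_setequal(filter_modules(m[, kept, drop = FALSE]), kept)
})

test_that("combined pathways average member modules", {
  defs <- c("K1 K2", "K3 K4 K5 K6")
  expect_equal(combined_pathway_completeness(defs, sprintf("K%d", 1:6)), 100)
  expect_equal(combined_pathway_completeness(defs, c("K3", "K4", "K5", "K6")),
               50)     # 0% and 100% members
  # step-weighted variant equals the direct weighted recomputation
  kos <- c("K1", "K3", "K4")
  c1 <- module_completeness(defs[1], kos)   # 50
  c2 <- module_completeness(defs[2], kos)   # 50
  expect_equal(combined_pathway_completeness(defs, kos, weights = "steps"),
               (c1 * 2 + c2 * 4) / 6)
  expect_error(combined_pathway_completeness(list(), "K1"), "empty")
})

test_that("KO densities per Mbp count distinct category members", {
  cmap <- data.frame(ko = c(sprintf("K%02d", 1:10), "K01"),
                     category = c(rep("sigma factor", 10), "flagellum"))
  dens <- kos_per_mbp(sprintf("K%02d", 1:10), cmap, 2e6)
  expect_equal(dens$kos_per_mbp[dens$category == "sigma factor"], 5)
  expect_equal(dens$kos_per_mbp[dens$category == "flagellum"], 0.5)
  dens0 <- kos_per_mbp(character(0), cmap, 2e6)
  expect_true(all(dens0$kos_per_mbp == 0))

  # brute-force recount on a simulated KO table
  cfg <- sim_config(n_species = 10L, n_samples = 2L, seed = 95L)
  cs <- simulate_catalog(cfg)
  mods <- synthetic_modules(n_modules = 10L, n_kos = 50L, seed = 3L)
  ko <- simulate_ko_table(cs, mods, cfg)
  cmap2 <- data.frame(ko = colnames(ko$ko_table),
                      category = rep(c("a", "b"),
                                     length.out = ncol(ko$ko_table)))
  g <- rownames(ko$ko_table)[1]
  held <- colnames(ko$ko_table)[ko$ko_table[g, ]]
  d <- kos_per_mbp(held, cmap2, 3e6)
  expect_equal(d$n_kos[d$category == "a"],
               length(intersect(held, cmap2$ko[cmap2$category == "a"])))
})

test_that("completeness matrices accept wide and long KO tables", {
  mods <- data.frame(module_id = c("M1", "M2"),
                     definition = c("K1 K2", "K1,K3"))
  wide <- matrix(c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE), 2, 3,
                 dimnames = list(c("g1", "g2"), c("K1", "K2", "K3")))
  cm <- completeness_matrix(mods, wide)
  expect_equal(cm["g1", "M1"], 50)    # g1 holds K1, K3
  expect_equal(cm["g1", "M2"], 100)
  expect_equal(cm["g2", "M1"], 100)   # g2 holds K1, K2
  long <- data.frame(genome = c("g1", "g1", "g2", "g2"),
                     ko = c("K1", "K3", "K1", "K2"))
  expect_equal(completeness_matrix(mods, long), cm)
})
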