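make_graph <- function(el) {
  cooccurrence_graph(data.frame(source = el[, 1], target = el[, 2]))
}

test_that("greedy modularity handles canonical small graphs", {
  # two disjoint triangles: two communities, Q = 2 * (3/6 - (6/12)^2) = 0.5
  tri2 <- make_graph(cbind(c("a", "b", "c", "d", "e", "f"),
                           c("b", "c", "a", "e", "f", "d")))
  res <- cluster_greedy_modularity(tri2)
  expect_equal(res$q, 0.5)
  expect_equal(length(unique(res$membership)), 2)
  expect_equal(length(unique(res$membership[c("a", "b", "c")])), 1)

  # complete graph K5: one community, Q = 0
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  res5 <- cluster_greedy_modularity(k5)
  expect_equal(res5$q, 0)
  expect_equal(length(unique(res5$membership)), 1)

  # edgeless graph: singletons with Q = 0
  g0 <- cooccurrence_graph(data.frame(source = character(0),
                                      target = character(0)),
                           nodes = c("x", "y", "z"))
  res0 <- cluster_greedy_modularity(g0)
  expect_equal(res0$q, 0)
  expect_equal(length(unique(res0$membership)), 3)
})

test_that("planted two-block graphs are recovered", {
  set.seed(81)
  g <- igraph::sample_sbm(40, pref.matrix = matrix(c(0.5, 0.05, 0.05, 0.5), 2),
                          block.sizes = c(20, 20))
  igraph::V(g)$name <- sprintf("n%02d", 1:40)
  res <- cluster_greedy_modularity(g)
  ari <- mclust::adjustedRandIndex(res$membership, rep(1:2, each = 20))
  expect_gte(ari, 0.9)
})

test_that("rewiring nulls preserve degrees and flag planted modularity", {
  set.seed(82)
  blocks <- igraph::sample_sbm(40, pref.matrix = matrix(c(0.6, 0.02, 0.02, 0.6),
                                                        2),
                               block.sizes = c(20, 20))
  igraph::V(blocks)$name <- sprintf("n%02d", 1:40)
  sig <- modularity_significance(blocks, n_perm = 199, rewiring_iters = 1000,
                                 seed = 1, check_degrees = TRUE)
  expect_equal(sig$p, 0)           # far more modular than any rewired null
  expect_equal(length(sig$null_q), 199)
  expect_true(all(sig$null_q < sig$q))

  # observed Q is at least the singleton and one-community partitions
  memb1 <- rep(1, igraph::vcount(blocks))
  membN <- seq_len(igraph::vcount(blocks))
  expect_gte(sig$q, igraph::modularity(blocks, memb1))
  expect_gte(sig$q, igraph::modularity(blocks, membN))
})

test_that("a single-edge graph cannot be rewired and gives p = 1", {
  g1 <- make_graph(cbind("a", "b"))
  expect_warning(sig <- modularity_significance(g1, n_perm = 20, seed = 3),
                 "rewiring")
  expect_equal(sig$p, 1)
})

test_that("cohort extraction applies the six-member threshold", {
  memb <- setNames(c(rep(1, 10), rep(2, 6), rep(3, 5)),
                   sprintf("s%02d", 1:21))
  co <- extract_cohorts(memb)
  expect_equal(unname(attr(co, "sizes")), c(10L, 6L))
  expect_equal(sum(co == "cohort_1"), 10)
  expect_equal(sum(co == "cohort_2"), 6)
  expect_equal(sum(co == "background"), 5)

  all_small <- extract_cohorts(setNames(rep(1:4, each = 3), 1:12))
  expect_true(all(all_small == "background"))

  # brute-force agreement on a random partition
  set.seed(83)
  memb_r <- setNames(sample(1:8, 60, replace = TRUE), sprintf("x%02d", 1:60))
  co_r <- extract_cohorts(memb_r, min_size = 6)
  tab <- table(memb_r)
  for (cl in names(tab)) {
    nodes <- names(memb_r)[memb_r == as.numeric(cl)]
    if (tab[cl] >= 6) {
      expect_equal(length(unique(co_r[nodes])), 1)
      expect_true(all(co_r[nodes] != "background"))
    } else {
      expect_true(all(co_r[nodes] == "background"))
    }
  }
})

test_that("within-cohort degree excludes cross-cohort edges", {
  # node a: 3 in-cohort neighbours, 2 cross-cohort
  el <- cbind(c("a", "a", "a", "a", "a", "b"),
              c("b", "c", "d", "x1", "x2", "c"))
  g <- make_graph(el)
  cohorts <- setNames(c("cohort_1", "cohort_1", "cohort_1", "cohort_1",
                        "cohort_2", "cohort_2"),
                      c("a", "b", "c", "d", "x1", "x2"))
  deg <- degree_within_cohort(g, cohorts)
  expect_equal(unname(deg["a"]), 3L)
  expect_equal(unname(deg["x1"]), 0L)   # x1's only edge (to a) is cross-cohort
})

test_that("within-cohort degree equals an adjacency-mask recomputation", {
  set.seed(84)
  g <- igraph::sample_gnp(30, 0.2)
  igraph::V(g)$name <- sprintf("v%02d", 1:30)
  cohorts <- setNames(sample(c("cohort_1", "cohort_2", "background"), 30,
                             replace = TRUE), igraph::V(g)$name)
  deg <- degree_within_cohort(g, cohorts)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  for (v in names(deg)) {
    same <- names(cohorts)[cohorts == cohorts[v]]
    expect_equal(unname(deg[v]), sum(A[v, same]))
  }
})

test_that("environmental preference is an abundance-weighted z-score mean", {
  ab <- matrix(1 / 6, 6, 4,
               dimnames = list(sprintf("s%d", 1:6), sprintf("m%d", 1:4)))
  cohorts <- setNames(c(rep("cohort_1", 3), rep("background", 3)),
                      rownames(ab))
  params <- data.frame(sample = colnames(ab), oxygen = c(1, 4, 7, 10))
  pref <- environmental_preference(ab, cohorts, params)
  # equal weight in every sample: preference is the mean z-score, zero
  expect_equal(unname(pref["cohort_1", "oxygen"]), 0, tolerance = 1e-12)

  # abundant only in high-oxygen samples: positive, equals brute force
  ab2 <- ab
  ab2[1:3, ] <- rep(c(0.001, 0.001, 0.3, 0.3), each = 3)
  pref2 <- environmental_preference(ab2, cohorts, params)
  z <- (params$oxygen - mean(params$oxygen)) / sd(params$oxygen)
  w <- colSums(ab2[1:3, ])
  expect_equal(unname(pref2["cohort_1", "oxygen"]), sum(w * z) / sum(w))
  expect_gt(pref2["cohort_1", "oxygen"], 0)
  # convex combination: bounded by the z-score range
  expect_gte(pref2["cohort_1", "oxygen"], min(z))
  expect_lte(pref2["cohort_1", "oxygen"], max(z))

  # single sample: sd undefined
  expect_warning(
    p1 <- environmental_preference(ab[, 1, drop = FALSE], cohorts,
                                   data.frame(sample = "m1", oxygen = 3)),
    "zero variance")
  expect_true(is.na(p1["cohort_1", "oxygen"]))
})

test_that("ARI scoring maps unmatched species to background", {
  truth <- setNames(c(rep("cohort_1", 4), rep("background", 4)),
                    sprintf("s%d", 1:8))
  rec <- setNames(rep("cohort_1", 4), sprintf("s%d", 1:4))
  expect_equal(cohort_recovery_ari(rec, truth), 1)
  rec_bad <- setNames(c("cohort_1", "cohort_1", "cohort_2", "cohort_2"),
                      sprintf("s%d", 1:4))
  expect_lt(cohort_recovery_ari(rec_bad, truth), 1)
})
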