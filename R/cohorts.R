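#' Build the co-occurrence graph from an edge list
#'
#' @param edges data.frame with `source` and `target` columns (output of
#'   [build_edges()]).
#' @param nodes Optional character vector of node names to include even
#'   when isolated.
#' @return An undirected simple `igraph` graph.
#' @export
cooccurrence_graph <- function(edges, nodes = NULL) {
  if (is.null(nodes)) {
    nodes <- sort(unique(c(edges$source, edges$target)))
  }
  g <- igraph::graph_from_data_frame(edges[, c("source", "target"),
                                           drop = FALSE],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  .check(igraph::is_simple(g), "graph must be simple (no loops/multi-edges)")
  g
}

#' Greedy modularity clustering (hierarchical agglomeration)
#'
#' Clauset-Newman-Moore greedy agglomeration: starting from singleton
#' communities, the merge with the largest modularity gain is applied
#' until no merge improves Q, and the partition at maximum Q is returned
#' together with Q itself (fraction of within-community edges minus its
#' expectation under the degree-preserving random graph). An edgeless
#' graph yields singleton communities with Q = 0.
#'
#' @param graph An undirected simple `igraph` graph.
#' @return List with `membership` (named integer vector) and `q`.
#' @export
cluster_greedy_modularity <- function(graph) {
  .check(igraph::vcount(graph) > 0, "empty graph")
  if (igraph::ecount(graph) == 0) {
    return(list(membership = setNames(seq_len(igraph::vcount(graph)),
                                      igraph::V(graph)$name),
                q = 0))
  }
  fc <- igraph::cluster_fast_greedy(graph)
  # cut the agglomeration dendrogram at the maximum-modularity step
  # (the first maximum: merging stops once no merge improves Q)
  memb <- igraph::cut_at(fc, steps = which.max(fc$modularity) - 1L)
  list(membership = setNames(as.integer(memb), igraph::V(graph)$name),
       q = igraph::modularity(graph, memb))
}

#' Modularity significance against degree-preserving rewired nulls
#'
#' Each permutation applies `rewiring_iters` attempted double-edge swaps
#' (rejecting swaps that would create loops or multi-edges), preserving
#' every node's degree exactly, then re-clusters the rewired graph with
#' [cluster_greedy_modularity()] and records its Q. The p-value is the
#' raw proportion of null Q values at least as large as the observed Q,
#' so p = 0 is attainable.
#'
#' @param graph An undirected simple `igraph` graph with >= 1 edge.
#' @param n_perm Number of rewired null networks (default 500).
#' @param rewiring_iters Attempted swaps per null network (default 1000).
#' @param seed Seed for the rewiring.
#' @param check_degrees Assert degree preservation on every permutation.
#' @return List with `q` (observed), `null_q` (length `n_perm`), `p`.
#' @export
modularity_significance <- function(graph, n_perm = 500L,
                                    rewiring_iters = 1000L, seed = NULL,
                                    check_degrees = TRUE) {
  .check(igraph::ecount(graph) >= 1, "graph has no edges")
  if (igraph::ecount(graph) < 2) {
    warning("fewer than 2 edges: no rewiring is possible, p = 1",
            call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- cluster_greedy_modularity(graph)
  deg <- igraph::degree(graph)
  null_q <- vapply(seq_len(n_perm), function(b) {
    gr <- igraph::rewire(graph,
                         igraph::keeping_degseq(loops = FALSE,
                                                niter = rewiring_iters))
    if (check_degrees) {
      .check(identical(igraph::degree(gr), deg),
             "rewiring changed the degree sequence")
    }
    cluster_greedy_modularity(gr)$q
  }, numeric(1))
  list(q = obs$q, null_q = null_q, p = mean(null_q >= obs$q),
       membership = obs$membership)
}

#' Extract cohorts from a community partition
#'
#' Communities with at least `min_size` members become cohorts, labeled
#' `cohort_1`, `cohort_2`, ... by descending size (ties by smallest
#' original community id); smaller communities are relabeled
#' `background` to remove spurious clusters.
#'
#' @param membership Named community membership vector.
#' @param min_size Minimum cohort size (default 6).
#' @return Named character vector of cohort labels, with attribute
#'   `sizes` (named sizes of the kept cohorts).
#' @export
extract_cohorts <- function(membership, min_size = 6L) {
  tab <- table(membership)
  keep <- names(tab)[tab >= min_size]
  ord <- keep[order(-tab[keep], as.numeric(keep))]
  out <- setNames(rep("background", length(membership)), names(membership))
  for (k in seq_along(ord)) {
    out[membership == as.numeric(ord[k])] <- sprintf("cohort_%d", k)
  }
  attr(out, "sizes") <- setNames(as.integer(tab[ord]),
                                 sprintf("cohort_%d", seq_along(ord)))
  out
}

#' Within-cohort degree of connectedness
#'
#' Node degree computed on the induced subgraph of each cohort:
#' cross-cohort edges and edges to background nodes are excluded.
#' Background nodes are omitted from the result.
#'
#' @param graph The co-occurrence `igraph` graph.
#' @param cohorts Named cohort labels from [extract_cohorts()].
#' @return Named integer vector of within-cohort degrees.
#' @export
degree_within_cohort <- function(graph, cohorts) {
  out <- integer(0)
  for (co in setdiff(unique(cohorts), "background")) {
    members <- names(cohorts)[cohorts == co]
    sub <- igraph::induced_subgraph(graph,
                                    intersect(members,
                                              igraph::V(graph)$name))
    d <- igraph::degree(sub)
    out <- c(out, setNames(as.integer(d), names(d)))
  }
  out
}

#' Environmental preference of each cohort
#'
#' Each environmental parameter is z-scored across samples (sample sd,
#' samples with missing values dropped per parameter), then averaged with
#' weights equal to the cohort's summed relative abundance per sample:
#' `pref(c, v) = sum_s w_cs z_vs / sum_s w_cs`. Positive values mean the
#' cohort is abundant above the parameter's baseline (e.g. oxygen-rich
#' samples), negative below. A parameter with zero sd is undefined (NA,
#' with a warning).
#'
#' @param abundance Species x sample relative-abundance matrix.
#' @param cohorts Named cohort labels covering (a subset of) the rownames.
#' @param params data.frame of per-sample parameter values; rows aligned
#'   to `colnames(abundance)` (a `sample` column, if present, is used to
#'   align and then dropped).
#' @return Cohort x parameter matrix of weighted-average z-scores.
#' @export
environmental_preference <- function(abundance, cohorts, params) {
  if ("sample" %in% names(params)) {
    rownames(params) <- params$sample
    params <- params[colnames(abundance),
                     setdiff(names(params), "sample"), drop = FALSE]
  }
  num <- vapply(params, is.numeric, logical(1))
  params <- params[, num, drop = FALSE]
  cos <- setdiff(sort(unique(cohorts)), "background")
  .check(length(cos) > 0, "no cohorts to score")
  out <- matrix(NA_real_, length(cos), ncol(params),
                dimnames = list(cos, names(params)))
  for (v in names(params)) {
    x <- params[[v]]
    ok <- !is.na(x)
    if (sum(ok) < 2 || sd(x[ok]) == 0) {
      warning(sprintf("parameter '%s' has zero variance: undefined", v),
              call. = FALSE)
      next
    }
    z <- (x[ok] - mean(x[ok])) / sd(x[ok])
    for (co in cos) {
      members <- intersect(names(cohorts)[cohorts == co],
                           rownames(abundance))
      w <- colSums(abundance[members, ok, drop = FALSE])
      .check(sum(w) > 0, "cohort %s has zero abundance everywhere", co)
      out[co, v] <- sum(w * z) / sum(w)
    }
  }
  out
}

#' End-to-end co-occurrence pipeline on an abundance matrix
#'
#' Chains the prefilter, SparCC, bootstrap p-values, edge thresholding,
#' greedy modularity clustering with its rewiring significance test, and
#' cohort extraction. This is the network arm of the analysis run on
#' estimated (or simulated) relative abundances.
#'
#' @param abundance Species x sample relative-abundance matrix.
#' @param min_samples,min_overall_abundance Passed to
#'   [sparcc_prefilter()].
#' @param n_boot Bootstraps for edge p-values.
#' @param rho_min,alpha Passed to [build_edges()].
#' @param min_size Passed to [extract_cohorts()].
#' @param n_perm,rewiring_iters Passed to [modularity_significance()].
#' @param seed Root seed for bootstraps and rewiring.
#' @return List with `filtered`, `rho`, `p`, `edges`, `graph`,
#'   `membership`, `q`, `q_pvalue`, `cohorts`, `degree`.
#' @export
cooccurrence_pipeline <- function(abundance, min_samples = 3L,
                                  min_overall_abundance = 1e-4,
                                  n_boot = 500L, rho_min = 0.4,
                                  alpha = 0.05, min_size = 6L,
                                  n_perm = 500L, rewiring_iters = 1000L,
                                  seed = 1L) {
  filtered <- sparcc_prefilter(abundance, min_samples,
                               min_overall_abundance)
  rho <- sparcc(filtered)
  p <- sparcc_bootstrap(filtered, rho, n_boot = n_boot, seed = seed)
  edges <- build_edges(rho, p, rho_min = rho_min, alpha = alpha)
  if (nrow(edges) == 0) {
    return(list(filtered = filtered, rho = rho, p = p, edges = edges,
                graph = NULL, membership = NULL, q = NA_real_,
                q_pvalue = NA_real_,
                cohorts = setNames(character(0), character(0)),
                degree = integer(0)))
  }
  graph <- cooccurrence_graph(edges)
  sig <- modularity_significance(graph, n_perm = n_perm,
                                 rewiring_iters = rewiring_iters,
                                 seed = seed + 1L)
  cohorts <- extract_cohorts(sig$membership, min_size = min_size)
  list(filtered = filtered, rho = rho, p = p, edges = edges, graph = graph,
       membership = sig$membership, q = sig$q, q_pvalue = sig$p,
       cohorts = cohorts, degree = degree_within_cohort(graph, cohorts))
}

#' Score planted-cohort recovery
#'
#' Compares recovered cohort labels with planted ground-truth labels via
#' the adjusted Rand index over all species (species absent from the
#' network count as background).
#'
#' @param recovered Named cohort labels from [extract_cohorts()].
#' @param truth Named planted labels (`"cohort_k"` / `"background"`).
#' @return Adjusted Rand index.
#' @export
cohort_recovery_ari <- function(recovered, truth) {
  all_sp <- names(truth)
  rec <- setNames(rep("background", length(all_sp)), all_sp)
  shared <- intersect(all_sp, names(recovered))
  rec[shared] <- recovered[shared]
  mclust::adjustedRandIndex(rec, truth[all_sp])
}
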