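#' Prevalence/abundance prefilter for co-occurrence inference
#'
#' Retains species detected (abundance > 0) in at least `min_samples`
#' samples whose overall relative abundance exceeds
#' `min_overall_abundance`. "Overall" defaults to the mean across all
#' samples; `max` and `sum` are selectable alternatives.
#'
#' @param abundance Species x sample relative-abundance matrix.
#' @param min_samples Minimum number of samples with detection.
#' @param min_overall_abundance Exclusive overall-abundance floor.
#' @param rule Overall-abundance summary: `"mean"`, `"max"` or `"sum"`.
#' @return The retained submatrix, with attribute `dropped` naming the
#'   excluded species. Warns when nothing survives.
#' @export
sparcc_prefilter <- function(abundance, min_samples = 3L,
                             min_overall_abundance = 1e-4,
                             rule = c("mean", "max", "sum")) {
  rule <- match.arg(rule)
  overall <- switch(rule,
                    mean = rowMeans(abundance),
                    max = apply(abundance, 1, max),
                    sum = rowSums(abundance))
  keep <- rowSums(abundance > 0) >= min_samples &
    overall > min_overall_abundance
  if (!any(keep)) warning("no species survive the prefilter", call. = FALSE)
  out <- abundance[keep, , drop = FALSE]
  attr(out, "dropped") <- rownames(abundance)[!keep]
  out
}

# Core SparCC basis-variance estimate on one fraction matrix (species x
# samples, columns summing to 1). Log-ratio variances
# t_ij = Var(log(x_i / x_j)) relate to basis variances w_i and
# correlations via t_ij = w_i + w_j - 2 rho_ij sqrt(w_i w_j); under the
# sparsity assumption the w solve the linear system M w = rowSums(T) with
# M = (D - 2) I + J. The most strongly correlated pair above
# `exclusion_threshold` is then excluded from the system and the solve
# repeated, up to `max_exclusions` times.
sparcc_basis <- function(fracs, exclusion_threshold = 0.1,
                         max_exclusions = NULL) {
  D <- nrow(fracs)
  if (is.null(max_exclusions)) max_exclusions <- max(D - 4L, 0L)
  L <- log(fracs)
  S <- cov(t(L))
  v <- diag(S)
  T <- outer(v, v, "+") - 2 * S
  diag(T) <- 0

  M <- matrix(1, D, D)
  diag(M) <- D - 1
  trow <- rowSums(T)

  rho_from <- function(w) {
    if (any(w <= 0)) {
      warning("non-positive basis variance; clamping", call. = FALSE)
      w <- pmax(w, .Machine$double.eps)
    }
    r <- (outer(w, w, "+") - T) / (2 * sqrt(outer(w, w)))
    r[r > 1] <- 1
    r[r < -1] <- -1
    diag(r) <- 1
    r
  }

  w <- solve(M, trow)
  rho <- rho_from(w)
  excluded <- matrix(FALSE, D, D)
  for (iter in seq_len(max_exclusions)) {
    cand <- abs(rho)
    cand[excluded | upper.tri(cand) == FALSE] <- -Inf  # upper triangle only
    top <- which(cand == max(cand), arr.ind = TRUE)[1, ]
    if (cand[top[1], top[2]] <= exclusion_threshold) break
    i <- top[1]; j <- top[2]
    excluded[i, j] <- excluded[j, i] <- TRUE
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    M[i, j] <- M[i, j] - 1
    M[j, i] <- M[j, i] - 1
    trow[i] <- trow[i] - T[i, j]
    trow[j] <- trow[j] - T[i, j]
    w <- solve(M, trow)
    rho <- rho_from(w)
  }
  dimnames(rho) <- dimnames(fracs)[c(1, 1)]
  rho
}

#' SparCC compositional correlations
#'
#' Estimates pairwise correlations between components of compositional
#' data from log-ratio variances under a sparsity assumption, which
#' removes the spurious negative bias plain correlations suffer on
#' closed (relative) data. When `counts = TRUE` the inputs are treated
#' as integer counts: each of `n_inner` iterations draws per-sample
#' fractions from a Dirichlet posterior (counts + 1) and the element-wise
#' median over iterations is returned. Relative-abundance input (the
#' default) is renormalized once per column and estimated in a single
#' deterministic pass.
#'
#' @param x Species x sample matrix of relative abundances (or counts).
#'   All entries must be positive after renormalization, >= 4 species
#'   and >= 3 samples.
#' @param counts Treat `x` as integer counts and resample fractions.
#' @param n_inner Inner Dirichlet iterations when `counts = TRUE`.
#' @param exclusion_threshold Correlation magnitude above which the
#'   strongest pair is iteratively excluded from the basis system.
#' @param max_exclusions Maximum excluded pairs (default `D - 4`).
#' @param seed Seed for the Dirichlet draws.
#' @return Symmetric correlation matrix in [-1, 1] with unit diagonal,
#'   with attributes `n_inner_iterations`, `exclusion_threshold`.
#' @export
sparcc <- function(x, counts = FALSE, n_inner = 50L,
                   exclusion_threshold = 0.1, max_exclusions = NULL,
                   seed = NULL) {
  .check(nrow(x) >= 4, "SparCC needs >= 4 species")
  .check(ncol(x) >= 3, "SparCC needs >= 3 samples")
  if (counts) {
    if (!is.null(seed)) set.seed(seed)
    rhos <- lapply(seq_len(n_inner), function(b) {
      g <- matrix(rgamma(length(x), shape = x + 1), nrow(x))
      f <- sweep(g, 2, colSums(g), "/")
      sparcc_basis(f, exclusion_threshold, max_exclusions)
    })
    rho <- apply(simplify2array(rhos), c(1, 2), median)
    dimnames(rho) <- dimnames(x)[c(1, 1)]
  } else {
    .check(all(x > 0), "relative-abundance input must be strictly positive")
    f <- sweep(x, 2, colSums(x), "/")
    rho <- sparcc_basis(f, exclusion_threshold, max_exclusions)
  }
  attr(rho, "n_inner_iterations") <- as.integer(n_inner)
  attr(rho, "exclusion_threshold") <- exclusion_threshold
  rho
}

#' Bootstrap p-values for SparCC correlations
#'
#' Each bootstrap independently permutes every species' abundances
#' across samples (destroying all between-species association while
#' keeping marginals), reruns SparCC with the same settings, and the
#' one-sided upper-tail p-value is the raw proportion of null
#' correlations at least as large as the observed one (so p = 0 is
#' attainable). Child seeds are derived deterministically from `seed`,
#' making bootstraps order-independent.
#'
#' @param x The filtered abundance (or count) matrix the observed
#'   correlations were computed on.
#' @param observed_rho Observed SparCC correlation matrix.
#' @param n_boot Number of bootstraps (>= 1).
#' @param seed Root seed.
#' @inheritParams sparcc
#' @return Symmetric p-value matrix in [0, 1] (diagonal 0) with
#'   attribute `n_boot`.
#' @export
sparcc_bootstrap <- function(x, observed_rho, n_boot = 500L, seed = 1L,
                             counts = FALSE, n_inner = 50L,
                             exclusion_threshold = 0.1,
                             max_exclusions = NULL) {
  .check(n_boot >= 1, "n_boot must be >= 1")
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, n_boot)
  ge_count <- matrix(0, nrow(x), nrow(x))
  for (b in seq_len(n_boot)) {
    set.seed(child[b])
    xb <- t(apply(x, 1, sample))
    null_rho <- suppressWarnings(
      sparcc(xb, counts = counts, n_inner = n_inner,
             exclusion_threshold = exclusion_threshold,
             max_exclusions = max_exclusions,
             seed = if (counts) child[b] else NULL))
    ge_count <- ge_count + (null_rho >= observed_rho)
  }
  p <- ge_count / n_boot
  diag(p) <- 0
  dimnames(p) <- dimnames(observed_rho)
  attr(p, "n_boot") <- as.integer(n_boot)
  p
}

#' Filtered positive co-occurrence edge list
#'
#' Keeps pairs with correlation strictly above `rho_min` and p-value
#' strictly below `alpha`; only positive co-occurrences are retained.
#'
#' @param rho Symmetric SparCC correlation matrix.
#' @param p Symmetric p-value matrix.
#' @param rho_min Exclusive correlation floor (default 0.4).
#' @param alpha Exclusive p-value ceiling (default 0.05).
#' @return data.frame with `source`, `target` (source < target), `rho`,
#'   `p`, sorted by source then target.
#' @export
build_edges <- function(rho, p, rho_min = 0.4, alpha = 0.05) {
  .check(all(dim(rho) == dim(p)), "rho and p matrices are not aligned")
  idx <- which(upper.tri(rho) & rho > rho_min & p < alpha, arr.ind = TRUE)
  nm <- rownames(rho)
  if (is.null(nm)) nm <- as.character(seq_len(nrow(rho)))
  out <- data.frame(source = nm[idx[, 1]], target = nm[idx[, 2]],
                    rho = rho[idx], p = p[idx], stringsAsFactors = FALSE)
  out[order(out$source, out$target), , drop = FALSE]
}
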