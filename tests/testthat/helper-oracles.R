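# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-derivations (explicit loops, different solve
# routes, a separate tree representation) kept independent of the
# package's implementation paths.

# truncated average depth: drop k highest, then k lowest, average the rest
oracle_tad <- function(v, cf = 0.8) {
  k <- floor(((1 - cf) / 2) * length(v) + 1e-9)
  s <- sort(v, decreasing = TRUE)
  if (k > 0) s <- s[-seq_len(k)]
  s <- rev(s)
  if (k > 0) s <- s[-seq_len(k)]
  sum(s) / length(s)
}

# textbook SparCC on a fraction matrix: explicit log-ratio variance
# loops, explicit inverse, same exclusion schedule
oracle_sparcc <- function(f, threshold = 0.1, max_excl = nrow(f) - 4L) {
  D <- nrow(f)
  T <- matrix(0, D, D)
  for (i in 1:D) for (j in 1:D) T[i, j] <- stats::var(log(f[i, ] / f[j, ]))
  M <- matrix(1, D, D); diag(M) <- D - 1
  t_i <- vapply(1:D, function(i) sum(T[i, ]), numeric(1))
  rho_of <- function(w) {
    r <- matrix(0, D, D)
    for (i in 1:D) for (j in 1:D) {
      r[i, j] <- (w[i] + w[j] - T[i, j]) / (2 * sqrt(w[i] * w[j]))
    }
    r <- pmin(pmax(r, -1), 1); diag(r) <- 1; r
  }
  w <- as.numeric(solve(M) %*% t_i)
  rho <- rho_of(w)
  excl <- matrix(FALSE, D, D)
  for (it in seq_len(max(max_excl, 0L))) {
    bi <- bj <- NA; bv <- threshold
    for (i in 1:(D - 1)) for (j in (i + 1):D) {
      if (!excl[i, j] && abs(rho[i, j]) > bv) {
        bv <- abs(rho[i, j]); bi <- i; bj <- j
      }
    }
    if (is.na(bi)) break
    excl[bi, bj] <- excl[bj, bi] <- TRUE
    M[bi, bi] <- M[bi, bi] - 1; M[bj, bj] <- M[bj, bj] - 1
    M[bi, bj] <- M[bi, bj] - 1; M[bj, bi] <- M[bj, bi] - 1
    t_i[bi] <- t_i[bi] - T[bi, bj]; t_i[bj] <- t_i[bj] - T[bi, bj]
    w <- as.numeric(solve(M) %*% t_i)
    rho <- rho_of(w)
  }
  rho
}

# ---- random module-definition trees in an independent representation ----
# node types: ko(id, opt) | alt(parts) | cpx(parts) | grp(steps, opt)

rand_module_tree <- function(universe, max_depth = 2L) {
  ko <- function(opt = FALSE) list(type = "ko", id = sample(universe, 1),
                                   opt = opt)
  atom <- function(depth) {
    if (depth < max_depth && runif(1) < 0.2) {
      list(type = "grp", steps = steps(depth + 1L), opt = FALSE)
    } else ko()
  }
  cpx <- function(depth) {
    n <- sample(2:3, 1)
    parts <- lapply(seq_len(n), function(i) atom(depth))
    for (i in seq_len(n)) parts[[i]]$opt <- i > 1 && runif(1) < 0.25
    list(type = "cpx", parts = parts)
  }
  alt <- function(depth) {
    n <- sample(2:3, 1)
    list(type = "alt", parts = lapply(seq_len(n), function(i) {
      r <- runif(1)
      if (r < 0.25) cpx(depth) else atom(depth)
    }))
  }
  one_step <- function(depth) {
    r <- runif(1)
    if (r < 0.40) atom(depth)
    else if (r < 0.65) alt(depth)
    else if (r < 0.90) cpx(depth)
    else { a <- atom(depth); a$opt <- TRUE; a }   # leading-minus step
  }
  steps <- function(depth) lapply(seq_len(sample(2:5, 1)),
                                  function(i) one_step(depth))
  list(type = "seq", steps = steps(0L))
}

render_module_tree <- function(node) {
  r <- function(n) {
    switch(n$type,
      ko = n$id,
      grp = paste0("(", paste(vapply(n$steps, function(s)
        paste0(if (isTRUE(s$opt)) "-" else "", r(s)), character(1)),
        collapse = " "), ")"),
      alt = paste(vapply(n$parts, r, character(1)), collapse = ","),
      cpx = paste0(vapply(seq_along(n$parts), function(i) {
        p <- n$parts[[i]]
        sep <- if (i == 1) "" else if (isTRUE(p$opt)) "-" else "+"
        paste0(sep, r(p))
      }, character(1)), collapse = ""))
  }
  paste(vapply(node$steps, function(s)
    paste0(if (isTRUE(s$opt)) "-" else "", r(s)), character(1)),
    collapse = " ")
}

# completeness of the tree under the strict step rule, computed on the
# generator's own representation
oracle_tree_completeness <- function(node, kos) {
  sat <- function(n) {
    switch(n$type,
      ko = n$id %in% kos,
      alt = any(vapply(n$parts, sat, logical(1))),
      cpx = {
        req <- Filter(function(p) !isTRUE(p$opt), n$parts)
        length(req) == 0 || all(vapply(req, sat, logical(1)))
      },
      grp = {
        req <- Filter(function(s) !step_opt(s), n$steps)
        length(req) == 0 || all(vapply(req, sat, logical(1)))
      })
  }
  step_opt <- function(s) {
    if (isTRUE(s$opt)) return(TRUE)
    if (s$type == "cpx") return(all(vapply(s$parts, function(p)
      isTRUE(p$opt), logical(1))))
    FALSE
  }
  req <- Filter(function(s) !step_opt(s), node$steps)
  if (length(req) == 0) return(NA_real_)
  100 * mean(vapply(req, sat, logical(1)))
}

# rank-based AUROC of positive vs negative scores
auroc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# mean within-cohort pairwise Pearson correlation of log abundances
mean_within_cohort_cor <- function(ab, labels) {
  vals <- c()
  for (co in setdiff(unique(labels), "background")) {
    m <- log(ab[names(labels)[labels == co], , drop = FALSE])
    cc <- stats::cor(t(m))
    vals <- c(vals, cc[upper.tri(cc)])
  }
  mean(vals)
}
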