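#' Simple linear regression with Pearson correlation and residuals
#'
#' Ordinary least squares of `y` on `x` with the Pearson correlation
#' coefficient, its square, and per-point residuals (used downstream to
#' compare cohorts against the overall trend, e.g. prevalence given
#' average relative abundance). A constant `y` yields slope 0 with
#' `pearson_r = NA` and `degenerate = TRUE`; constant `x` is an error.
#'
#' @param x,y Numeric vectors with >= 3 finite pairs.
#' @return List of class `regression_result`: `slope`, `intercept`,
#'   `pearson_r`, `r_squared`, `residuals`, `n`, `degenerate`.
#' @export
linear_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  .check(sum(ok) >= 3, "need >= 3 finite (x, y) pairs")
  x <- x[ok]; y <- y[ok]
  .check(sd(x) > 0, "zero variance in x: fit undefined")
  fit <- lm(y ~ x)
  degenerate <- sd(y) == 0
  r <- if (degenerate) NA_real_ else cor(x, y)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 pearson_r = r,
                 r_squared = if (degenerate) NA_real_ else r^2,
                 residuals = unname(resid(fit)),
                 n = length(x), degenerate = degenerate),
            class = "regression_result")
}

# compact letter display from a logical "significantly different" matrix
# (insert-and-absorb): groups sharing a letter are not significantly
# different
.letter_display <- function(diff_mat) {
  g <- rownames(diff_mat)
  sets <- list(g)
  prs <- which(diff_mat & upper.tri(diff_mat), arr.ind = TRUE)
  for (r in seq_len(nrow(prs))) {
    a <- g[prs[r, 1]]; b <- g[prs[r, 2]]
    out <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        out <- c(out, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        out <- c(out, list(s))
      }
    }
    out <- unique(lapply(out[vapply(out, length, integer(1)) > 0], sort))
    keep <- vapply(seq_along(out), function(i)    # drop contained sets
      !any(vapply(seq_along(out), function(j)
        j != i && all(out[[i]] %in% out[[j]]), logical(1))), logical(1))
    sets <- out[keep]
  }
  # order letters by each set's first group for a stable display
  sets <- sets[order(vapply(sets, function(s) match(s[1], g), integer(1)))]
  letters_out <- setNames(rep("", length(g)), g)
  for (k in seq_along(sets)) {
    for (m in sets[[k]]) {
      letters_out[m] <- paste0(letters_out[m], letters[k])
    }
  }
  letters_out
}

#' Kruskal-Wallis test with Benjamini-Hochberg-corrected pairwise
#' comparisons
#'
#' Overall rank-based Kruskal-Wallis H test (tie-corrected) across
#' groups, followed by pairwise Wilcoxon rank-sum tests whose p-values
#' are Benjamini-Hochberg adjusted over the pairwise family, plus a
#' compact letter display in which groups sharing a letter do not differ
#' at `alpha`.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length.
#' @param alpha Significance level for the letter display.
#' @return List of class `group_test_result`: `h`, `p` (overall),
#'   `pairwise` (data.frame `group1`, `group2`, `p_raw`, `p_adj`),
#'   `letters` (named character).
#' @export
kruskal_wallis_bh <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  .check(all(table(groups)[gl] >= 1), "each group needs >= 1 observation")
  if (length(gl) < 2) {
    return(structure(list(h = NA_real_, p = NA_real_,
                          pairwise = data.frame(),
                          letters = setNames("a", gl)),
                     class = "group_test_result"))
  }
  kw <- kruskal.test(values, factor(groups))
  combs <- utils::combn(gl, 2)
  p_raw <- apply(combs, 2, function(pr) {
    suppressWarnings(wilcox.test(values[groups == pr[1]],
                                 values[groups == pr[2]],
                                 exact = FALSE)$p.value)
  })
  p_adj <- p.adjust(p_raw, method = "BH")
  pw <- data.frame(group1 = combs[1, ], group2 = combs[2, ],
                   p_raw = p_raw, p_adj = p_adj, stringsAsFactors = FALSE)
  diff_mat <- matrix(FALSE, length(gl), length(gl),
                     dimnames = list(gl, gl))
  sig <- !is.na(p_adj) & p_adj < alpha
  diff_mat[cbind(combs[1, sig], combs[2, sig])] <- TRUE
  diff_mat[cbind(combs[2, sig], combs[1, sig])] <- TRUE
  structure(list(h = unname(kw$statistic), p = kw$p.value, pairwise = pw,
                 letters = .letter_display(diff_mat)),
            class = "group_test_result")
}

#' Z-score standardization
#'
#' `(x - mean(x)) / sd(x)` with the sample (n - 1) standard deviation.
#'
#' @param x Numeric vector with `sd(x) > 0`.
#' @return Standardized vector (mean 0, sd 1).
#' @export
zscore <- function(x) {
  .check(sum(is.finite(x)) >= 2, "need >= 2 finite values")
  s <- sd(x, na.rm = TRUE)
  .check(s > 0, "sd(x) = 0: z-score undefined")
  (x - mean(x, na.rm = TRUE)) / s
}

#' Coefficient of variation, percent
#'
#' `sd(x) / mean(x) * 100` with the sample standard deviation.
#'
#' @param x Numeric vector.
#' @return CV in percent.
#' @export
cv_percent <- function(x) {
  sd(x) / mean(x) * 100
}

#' Assemble the per-run report tables
#'
#' Writes the study-style summary tables computed from upstream stage
#' outputs: genome size vs prevalence and vs average relative abundance
#' (with regression stats), genus-level size variability, cohort
#' membership / within-cohort degree / environmental preferences, module
#' completeness summaries, and a JSON manifest recording seeds,
#' thresholds and decision flags. Tables are plain TSV; a fixed-seed run
#' reproduces them byte-identically. Missing optional stages (e.g. no
#' cohorts) yield empty sections, not errors.
#'
#' @param run List of stage outputs: requires `catalog` and
#'   `prevalence` (from [prevalence_and_average()]); optional `cohorts`,
#'   `degree`, `preferences`, `completeness`, `config`.
#' @param out_dir Output directory, created if needed.
#' @return Named list of the report tables, invisibly.
#' @export
build_report <- function(run, out_dir) {
  .check(!is.null(run$catalog), "missing upstream artifact: catalog")
  .check(!is.null(run$prevalence), "missing upstream artifact: prevalence")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list()

  size <- setNames(run$catalog$estimated_size, run$catalog$id)
  prev <- run$prevalence
  prev$estimated_size <- unname(size[prev$species])
  tables$size_vs_prevalence <- prev[, c("species", "estimated_size",
                                        "prevalence", "avg_abundance")]
  fits <- list()
  if (sum(is.finite(prev$estimated_size)) >= 3 &&
      sd(prev$prevalence) > 0) {
    f1 <- linear_fit(prev$estimated_size / 1e6, prev$prevalence)
    f2 <- linear_fit(prev$estimated_size / 1e6, prev$avg_abundance)
    fits <- list(size_vs_prevalence = f1[c("slope", "intercept",
                                           "pearson_r", "r_squared", "n")],
                 size_vs_avg_abundance = f2[c("slope", "intercept",
                                              "pearson_r", "r_squared",
                                              "n")])
  }

  tables$genus_variability <- genus_variability(run$catalog)

  if (!is.null(run$cohorts) && length(run$cohorts) > 0) {
    co <- data.frame(species = names(run$cohorts),
                     cohort = unname(run$cohorts),
                     stringsAsFactors = FALSE)
    if (!is.null(run$degree)) {
      co$degree <- unname(run$degree[co$species])
    }
    tables$cohort_membership <- co
  } else {
    tables$cohort_membership <- data.frame(species = character(0),
                                           cohort = character(0))
  }
  if (!is.null(run$preferences)) {
    pr <- as.data.frame(run$preferences)
    pr <- cbind(cohort = rownames(pr), pr)
    rownames(pr) <- NULL
    tables$environmental_preference <- pr
  }
  if (!is.null(run$completeness)) {
    cm <- run$completeness
    tables$module_summary <- data.frame(
      module_id = colnames(cm),
      mean_completeness = colMeans(cm, na.rm = TRUE),
      frac_complete = colMeans(cm == 100, na.rm = TRUE),
      frac_positive = colMeans(cm > 0, na.rm = TRUE),
      row.names = NULL, stringsAsFactors = FALSE)
  }

  for (nm in names(tables)) {
    data.table::fwrite(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                       sep = "\t")
  }
  manifest <- list(
    tables = names(tables),
    regressions = fits,
    n_species = nrow(run$catalog),
    thresholds = list(quality = c(min_completeness = 0.5,
                                  max_contamination = 0.05),
                      edge = c(rho_min = 0.4, alpha = 0.05),
                      cohort_min_size = 6,
                      detection = "abundance > 0",
                      avg_abundance_over = "detected samples"),
    config = if (!is.null(run$config)) unclass(run$config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(tables)
}
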