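#' Parse a KEGG module DEFINITION string
#'
#' DEFINITION grammar: space-separated reaction steps; within a step,
#' commas separate alternative branches; `+` joins subunits of a complex
#' (all required); a `-` prefix marks an optional component that never
#' reduces completeness; parentheses group a sub-sequence evaluated as a
#' unit. Operator precedence is minus > plus > comma > space.
#'
#' @param defn Non-empty definition string over KO identifiers and the
#'   operators above.
#' @return A `module_definition`: a nested list of nodes with `kind` in
#'   `"seq"`, `"alt"`, `"complex"`, `"ko"`, each carrying an `optional`
#'   flag. Unbalanced parentheses or dangling operators raise a parse
#'   error reporting the character position.
#' @export
#' @examples
#' parse_definition("K00001 (K00002,K00003) K00004+K00005-K00006")
parse_definition <- function(defn) {
  .check(is.character(defn) && length(defn) == 1 && nzchar(trimws(defn)),
         "definition must be a non-empty string")
  m <- gregexpr("[A-Za-z0-9_.]+|[(),+ -]", defn)[[1]]
  tok <- regmatches(defn, list(m))[[1]]
  pos <- as.integer(m)
  if (sum(nchar(tok)) != nchar(defn)) {
    covered <- unlist(mapply(function(p, l) p:(p + l - 1), pos, nchar(tok),
                             SIMPLIFY = FALSE))
    bad <- setdiff(seq_len(nchar(defn)), covered)[1]
    stop(sprintf("parse error at position %d: unexpected character '%s'",
                 bad, substr(defn, bad, bad)), call. = FALSE)
  }
  env <- new.env()
  env$i <- 1L
  peek <- function() if (env$i <= length(tok)) tok[env$i] else NA_character_
  advance <- function() { t <- tok[env$i]; env$i <- env$i + 1L; t }
  err <- function(what) {
    p <- if (env$i <= length(tok)) pos[env$i] else nchar(defn) + 1L
    stop(sprintf("parse error at position %d: %s", p, what), call. = FALSE)
  }
  skip_space <- function() while (identical(peek(), " ")) advance()
  is_op <- function(t) !is.na(t) && t %in% c("(", ")", ",", "+", "-", " ")

  node <- function(kind, children = list(), ko = NULL, optional = FALSE) {
    list(kind = kind, children = children, ko = ko, optional = optional)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) err("unexpected end of definition")
    if (t == "(") {
      advance()
      e <- parse_expr()
      if (!identical(peek(), ")")) err("unbalanced parenthesis")
      advance()
      return(e)
    }
    if (is_op(t)) err(sprintf("dangling operator '%s'", t))
    advance()
    node("ko", ko = t)
  }
  parse_complex <- function() {
    first_opt <- FALSE
    if (identical(peek(), "-")) { advance(); first_opt <- TRUE }
    a <- parse_atom()
    a$optional <- first_opt
    parts <- list(a)
    while (!is.na(peek()) && peek() %in% c("+", "-")) {
      op <- advance()
      b <- parse_atom()
      b$optional <- op == "-"
      parts[[length(parts) + 1L]] <- b
    }
    if (length(parts) == 1L) return(parts[[1L]])
    node("complex", children = parts)
  }
  parse_step <- function() {
    alts <- list(parse_complex())
    while (identical(peek(), ",")) {
      advance()
      alts[[length(alts) + 1L]] <- parse_complex()
    }
    if (length(alts) == 1L) return(alts[[1L]])
    node("alt", children = alts)
  }
  parse_expr <- function() {
    skip_space()
    steps <- list(parse_step())
    repeat {
      if (!identical(peek(), " ")) break
      skip_space()
      if (is.na(peek()) || identical(peek(), ")")) break
      steps[[length(steps) + 1L]] <- parse_step()
    }
    node("seq", children = steps)
  }
  root <- parse_expr()
  skip_space()
  if (!is.na(peek())) err(sprintf("unexpected token '%s'", peek()))
  structure(root, class = "module_definition")
}

#' Serialize a parsed module definition back to a canonical string
#'
#' Inverse of [parse_definition()]: `parse_definition(format_definition(d))`
#' yields a tree equivalent to `d`.
#'
#' @param def A `module_definition` (or internal node).
#' @return Canonical definition string.
#' @export
format_definition <- function(def) {
  # body of a node, without its own optional prefix; nested sequences
  # (parenthesized groups) are re-wrapped in parentheses
  body <- function(n, depth) {
    switch(n$kind,
      ko = n$ko,
      seq = {
        s <- paste(vapply(n$children, function(ch)
          paste0(if (isTRUE(ch$optional)) "-" else "", body(ch, depth + 1L)),
          character(1)), collapse = " ")
        if (depth > 0L) paste0("(", s, ")") else s
      },
      alt = paste(vapply(n$children, function(ch)
        paste0(if (isTRUE(ch$optional)) "-" else "", body(ch, depth + 1L)),
        character(1)), collapse = ","),
      complex = paste0(vapply(seq_along(n$children), function(i) {
        ch <- n$children[[i]]
        sep <- if (i == 1L) { if (isTRUE(ch$optional)) "-" else "" }
               else if (isTRUE(ch$optional)) "-" else "+"
        paste0(sep, body(ch, depth + 1L))
      }, character(1)), collapse = ""),
      stop("unknown node kind"))
  }
  body(def, 0L)
}

#' KO identifiers appearing in a module definition
#'
#' @param def A `module_definition`.
#' @return Character vector of distinct KO ids (optional ones included).
#' @export
definition_kos <- function(def) {
  walk <- function(n) {
    if (n$kind == "ko") return(n$ko)
    unlist(lapply(n$children, walk))
  }
  unique(walk(def))
}

# is a node effectively optional (explicit flag, or a complex whose
# parts are all optional)?
.node_optional <- function(n) {
  if (isTRUE(n$optional)) return(TRUE)
  if (n$kind == "complex") {
    return(all(vapply(n$children, .node_optional, logical(1))))
  }
  FALSE
}

# strict recursive satisfaction of one node given a KO set
.satisfied <- function(n, kos) {
  switch(n$kind,
    ko = n$ko %in% kos,
    alt = any(vapply(n$children, .satisfied, logical(1), kos = kos)),
    complex = {
      req <- Filter(function(ch) !isTRUE(ch$optional), n$children)
      length(req) == 0L ||
        all(vapply(req, .satisfied, logical(1), kos = kos))
    },
    seq = {
      req <- Filter(function(ch) !.node_optional(ch), n$children)
      length(req) == 0L ||
        all(vapply(req, .satisfied, logical(1), kos = kos))
    })
}

# fractional score of one node (anvi'o-style nested averaging)
.fractional <- function(n, kos) {
  switch(n$kind,
    ko = as.numeric(n$ko %in% kos),
    alt = max(vapply(n$children, .fractional, numeric(1), kos = kos)),
    complex = {
      req <- Filter(function(ch) !isTRUE(ch$optional), n$children)
      if (length(req) == 0L) 1
      else mean(vapply(req, .fractional, numeric(1), kos = kos))
    },
    seq = {
      req <- Filter(function(ch) !.node_optional(ch), n$children)
      if (length(req) == 0L) 1
      else mean(vapply(req, .fractional, numeric(1), kos = kos))
    })
}

#' Module completeness for a genome's KO set
#'
#' Default (`mode = "strict"`): completeness is 100 x the fraction of
#' satisfied non-optional top-level steps, where a step is satisfied
#' recursively — an alternative if any branch is, a complex if all
#' non-optional subunits are present, a parenthesized group only if its
#' own sequence is fully complete. Optional (minus-prefixed) components
#' never reduce completeness and are excluded from denominators.
#' `mode = "fractional"` instead averages partial credit through nested
#' groups and complexes.
#'
#' @param def A `module_definition` (or a definition string, parsed on
#'   the fly).
#' @param kos Character vector of KO ids present in the genome.
#' @param mode `"strict"` (default) or `"fractional"`.
#' @return Completeness percent in [0, 100]; `NA` for a module with no
#'   non-optional steps (undefined).
#' @export
#' @examples
#' module_completeness("K00001 K00002 K00003", c("K00001", "K00002"))  # 66.7
module_completeness <- function(def, kos, mode = c("strict", "fractional")) {
  mode <- match.arg(mode)
  if (is.character(def)) def <- parse_definition(def)
  steps <- def$children
  req <- Filter(function(ch) !.node_optional(ch), steps)
  if (length(req) == 0L) return(NA_real_)
  if (mode == "strict") {
    100 * mean(vapply(req, .satisfied, logical(1), kos = kos))
  } else {
    100 * mean(vapply(req, .fractional, numeric(1), kos = kos))
  }
}

#' Genome x module completeness matrix
#'
#' @param modules data.frame with `module_id` and `definition` columns.
#' @param ko_table Either a logical genome x KO matrix or a long
#'   data.frame with columns `genome` and `ko`.
#' @param mode Passed to [module_completeness()].
#' @return Genome x module numeric matrix of completeness percent.
#' @export
completeness_matrix <- function(modules, ko_table,
                                mode = c("strict", "fractional")) {
  mode <- match.arg(mode)
  defs <- lapply(modules$definition, parse_definition)
  names(defs) <- modules$module_id
  if (is.data.frame(ko_table)) {
    held <- split(as.character(ko_table$ko), ko_table$genome)
  } else {
    held <- apply(ko_table, 1, function(row) colnames(ko_table)[row],
                  simplify = FALSE)
  }
  out <- t(vapply(held, function(k)
    vapply(defs, module_completeness, numeric(1), kos = k, mode = mode),
    numeric(length(defs))))
  dimnames(out) <- list(names(held), names(defs))
  out
}

#' Module retention filters
#'
#' A module is retained when (1) at least one genome has the complete
#' pathway (100% completeness) and (2) at least `min_frac` of the genomes
#' have completeness above 0% for it. Both filters act per module, so the
#' result is idempotent and order-independent.
#'
#' @param completeness Genome x module completeness matrix (percent).
#' @param min_frac Minimum fraction of genomes with completeness > 0
#'   (default 0.2).
#' @return Character vector of retained module ids.
#' @export
filter_modules <- function(completeness, min_frac = 0.2) {
  any100 <- apply(completeness, 2, function(x) any(x == 100, na.rm = TRUE))
  frac_pos <- apply(completeness, 2,
                    function(x) mean(x > 0, na.rm = TRUE))
  colnames(completeness)[any100 & frac_pos >= min_frac]
}

#' Completeness of a combined (multi-module) pathway
#'
#' Pathways spanning several modules (e.g. a corrinoid core plus an
#' aerobic or anaerobic branch) are scored as the unweighted mean of
#' member-module completeness; `weights = "steps"` instead weights each
#' member by its number of non-optional top-level steps.
#'
#' @param defs List of `module_definition`s (or definition strings).
#' @param kos KO ids present in the genome.
#' @param weights `"equal"` (default) or `"steps"`.
#' @param mode Passed to [module_completeness()].
#' @return Combined completeness percent.
#' @export
combined_pathway_completeness <- function(defs, kos,
                                          weights = c("equal", "steps"),
                                          mode = c("strict", "fractional")) {
  weights <- match.arg(weights)
  mode <- match.arg(mode)
  .check(length(defs) > 0, "empty module list")
  defs <- lapply(defs, function(d)
    if (is.character(d)) parse_definition(d) else d)
  comp <- vapply(defs, module_completeness, numeric(1), kos = kos,
                 mode = mode)
  if (weights == "equal") return(mean(comp, na.rm = TRUE))
  n_steps <- vapply(defs, function(d)
    length(Filter(function(ch) !.node_optional(ch), d$children)),
    numeric(1))
  sum(comp * n_steps, na.rm = TRUE) / sum(n_steps[!is.na(comp)])
}

#' Functional density: distinct KOs per Mbp by category
#'
#' @param kos KO ids present in the genome.
#' @param category_map data.frame with columns `ko` and `category`
#'   (a KO may appear under several categories).
#' @param estimated_size Estimated genome size in bp (> 0).
#' @return data.frame with `category`, `n_kos`, `kos_per_mbp` (zero-count
#'   categories included).
#' @export
kos_per_mbp <- function(kos, category_map, estimated_size) {
  .check(estimated_size > 0, "estimated_size must be > 0")
  cats <- sort(unique(category_map$category))
  n <- vapply(cats, function(cc)
    length(intersect(unique(category_map$ko[category_map$category == cc]),
                     kos)), integer(1))
  data.frame(category = cats, n_kos = n,
             kos_per_mbp = n / (estimated_size / 1e6),
             stringsAsFactors = FALSE, row.names = NULL)
}
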