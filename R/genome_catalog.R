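#' Estimate genome size from assembly size and completeness
#'
#' The size of the complete genome is estimated by dividing the assembly
#' size by its completeness (a fraction in (0, 1]), the standard
#' correction for partial metagenome-assembled genomes. Vectorized.
#'
#' @param assembly_size Assembly size(s) in bp, > 0.
#' @param completeness Completeness fraction(s) in (0, 1].
#' @return Estimated genome size(s) in bp; always >= `assembly_size`.
#' @export
#' @examples
#' estimate_genome_size(1.7e6, 0.85)  # 2 Mbp
estimate_genome_size <- function(assembly_size, completeness) {
  .check(all(assembly_size > 0), "assembly_size must be > 0")
  .check(all(completeness > 0 & completeness <= 1),
         "completeness must lie in (0, 1]")
  assembly_size / completeness
}

#' Filter a genome catalog on quality
#'
#' Retains genomes with completeness strictly greater than
#' `min_completeness` and contamination strictly less than
#' `max_contamination`. The defaults select medium-to-high quality
#' (> 50% complete, < 5% contaminated); `min_completeness = 0.9` gives
#' the high-quality tier used for metabolic scoring.
#'
#' @param catalog data.frame with `completeness` and `contamination`
#'   columns (fractions).
#' @param min_completeness Exclusive lower completeness bound.
#' @param max_contamination Exclusive upper contamination bound.
#' @return The retained subset of `catalog`.
#' @export
filter_quality <- function(catalog, min_completeness = 0.5,
                           max_contamination = 0.05) {
  .check(min_completeness >= 0 && min_completeness <= 1 &&
           max_contamination >= 0 && max_contamination <= 1,
         "thresholds must lie in [0, 1]")
  catalog[catalog$completeness > min_completeness &
            catalog$contamination < max_contamination, , drop = FALSE]
}

#' Dereplicate genomes into species-clusters by ANI
#'
#' Quality-sorted greedy clustering: genomes are ranked by completeness
#' (descending), contamination (ascending), assembly size (descending)
#' and id (ascending, for determinism); each still-unassigned genome in
#' rank order seeds a cluster and absorbs every unassigned genome whose
#' ANI to the seed exceeds `threshold`. The seed — by construction the
#' highest-quality member — is the cluster representative. Greedy
#' seeding avoids the chaining that single-linkage components allow.
#'
#' @param catalog Genome catalog data.frame (`id`, `completeness`,
#'   `contamination`, `assembly_size`).
#' @param ani data.frame with columns `id1`, `id2`, `ani` (percent).
#'   Treated as symmetric; absent pairs are below threshold.
#' @param threshold ANI percent; pairs with ANI strictly greater are
#'   clustered (default 95, the operational species boundary).
#' @return data.frame with columns `genome` and `representative`; the
#'   clusters partition the catalog.
#' @export
dereplicate <- function(catalog, ani, threshold = 95) {
  .check(!anyDuplicated(catalog$id), "duplicate genome ids")
  ids <- catalog$id
  ord <- order(-catalog$completeness, catalog$contamination,
               -catalog$assembly_size, catalog$id)
  # adjacency above threshold, symmetric
  keep <- ani$ani > threshold & ani$id1 %in% ids & ani$id2 %in% ids
  a <- ani[keep, , drop = FALSE]
  adj <- split(c(a$id2, a$id1), c(a$id1, a$id2))
  rep_of <- setNames(rep(NA_character_, length(ids)), ids)
  for (g in ids[ord]) {
    if (!is.na(rep_of[g])) next
    rep_of[g] <- g
    nb <- adj[[g]]
    if (!is.null(nb)) {
      nb <- nb[is.na(rep_of[nb])]
      rep_of[nb] <- g
    }
  }
  data.frame(genome = ids, representative = unname(rep_of[ids]),
             stringsAsFactors = FALSE)
}

#' Split a GTDB-style taxonomy string into rank columns
#'
#' @param taxonomy Character vector of `d__...;p__...;...;s__...` strings.
#' @return data.frame with columns `domain`, `phylum`, `class`, `order`,
#'   `family`, `genus`, `species` (NA where a rank is missing).
#' @export
parse_taxonomy <- function(taxonomy) {
  ranks <- c(d = "domain", p = "phylum", c = "class", o = "order",
             f = "family", g = "genus", s = "species")
  out <- lapply(strsplit(taxonomy, ";", fixed = TRUE), function(parts) {
    parts <- trimws(parts)
    got <- setNames(rep(NA_character_, length(ranks)), ranks)
    pre <- sub("__.*$", "", parts)
    val <- sub("^.__", "", parts)
    ok <- pre %in% names(ranks)
    got[ranks[pre[ok]]] <- ifelse(nzchar(val[ok]), val[ok], NA_character_)
    got
  })
  as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
}

#' Genus-level genome-size variability
#'
#' For every genus represented by at least `min_members` species-cluster
#' representatives, computes the mean, sample standard deviation (n - 1
#' denominator), variance (sd^2) and coefficient of variation
#' (sd / mean * 100) of estimated genome sizes. Genera below the member
#' cutoff are omitted.
#'
#' @param catalog data.frame of cluster representatives with
#'   `estimated_size` and either a `genus` column or a `taxonomy` string.
#' @param min_members Minimum species-clusters per genus (default 5).
#' @return data.frame with `genus`, `n_clusters`, `mean_size`, `sd_size`,
#'   `variance`, `cv`.
#' @export
genus_variability <- function(catalog, min_members = 5L) {
  genus <- if ("genus" %in% names(catalog)) catalog$genus
           else parse_taxonomy(catalog$taxonomy)$genus
  keep <- !is.na(genus)
  sizes <- split(catalog$estimated_size[keep], genus[keep])
  sizes <- sizes[vapply(sizes, length, integer(1)) >= min_members]
  out <- data.frame(
    genus = names(sizes),
    n_clusters = vapply(sizes, length, integer(1)),
    mean_size = vapply(sizes, mean, numeric(1)),
    sd_size = vapply(sizes, sd, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out$variance <- out$sd_size^2
  out$cv <- out$sd_size / out$mean_size * 100
  out[order(out$genus), , drop = FALSE]
}

#' Assembly size from a FASTA file
#'
#' Sums sequence lengths of a (multi-)FASTA assembly; used when the
#' catalog table lacks assembly sizes. Requires the Biostrings package.
#'
#' @param path FASTA file path.
#' @return Total assembly size in bp.
#' @export
assembly_size_from_fasta <- function(path) {
  .check(requireNamespace("Biostrings", quietly = TRUE),
         "assembly_size_from_fasta requires the Biostrings package")
  sum(Biostrings::width(Biostrings::readDNAStringSet(path)))
}
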