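#' Truncated average depth (TAD)
#'
#' Sorts the positional depth distribution (zero-depth positions
#' included), drops `floor(((1 - central_fraction) / 2) * L)` positions
#' from each tail, and returns the arithmetic mean of the remainder. With
#' the default `central_fraction = 0.8` this is TAD80: the mean depth
#' after discarding the 10% highest and 10% lowest positions, which makes
#' the abundance signal robust to mapping pile-ups on conserved regions
#' and to sparse spurious hits.
#'
#' @param depths Non-empty numeric vector of positional (or per-window)
#'   depths.
#' @param central_fraction Central fraction retained, in (0, 1].
#' @return The truncated average depth.
#' @export
#' @examples
#' tad(c(0, 0, 1, 1, 1, 1, 1, 1, 9, 9))  # 1.875
tad <- function(depths, central_fraction = 0.8) {
  .check(length(depths) > 0, "empty depth vector")
  .check(central_fraction > 0 && central_fraction <= 1,
         "central_fraction must lie in (0, 1]")
  L <- length(depths)
  # guard against binary representation error (1 - 0.8 < 0.2) before floor
  k <- floor((1 - central_fraction) / 2 * L + sqrt(.Machine$double.eps))
  s <- sort(depths)
  mean(s[(k + 1):(L - k)])
}

#' Average genome size from single-copy marker hits
#'
#' The community's average genome size is inversely proportional to the
#' number of reads hitting universal single-copy marker genes:
#' `AGS_m = c_m * total_bp / hits_m` per marker family, with `c_m` the
#' marker's known calibration constant; the estimate is the median over
#' marker families with at least one hit. Doubling `total_bp` and hits
#' jointly leaves the estimate unchanged.
#'
#' @param total_bp Total sequenced bp in the sample.
#' @param marker_hits Named vector of hit counts per marker family.
#' @param calibration Named vector of per-marker constants `c_m`, aligned
#'   to `marker_hits` by name.
#' @return Average genome size estimate in bp.
#' @export
estimate_avg_genome_size <- function(total_bp, marker_hits, calibration) {
  .check(total_bp > 0, "total_bp must be > 0")
  nm <- names(marker_hits)
  if (!is.null(nm) && !is.null(names(calibration))) {
    calibration <- calibration[nm]
  }
  .check(length(calibration) == length(marker_hits),
         "calibration constants do not align with marker hits")
  ok <- marker_hits > 0
  .check(any(ok), "no marker family received any hits")
  median(calibration[ok] * total_bp / marker_hits[ok])
}

#' Genome equivalents of a metagenome
#'
#' Total sequenced bp divided by the community's average genome size: the
#' number of "average genomes" worth of sequence in the sample, the
#' normalizer that converts a genome's coverage into relative abundance.
#'
#' @param total_bp Total sequenced bp (> 0).
#' @param avg_genome_size Average genome size in bp (> 0).
#' @return Dimensionless genome equivalents.
#' @export
genome_equivalents <- function(total_bp, avg_genome_size) {
  .check(all(total_bp > 0) && all(avg_genome_size > 0),
         "total_bp and avg_genome_size must be > 0")
  total_bp / avg_genome_size
}

#' Relative abundance from TAD and genome equivalents
#'
#' @param tad80 Truncated average depth (>= 0).
#' @param ge Genome equivalents (> 0).
#' @return Relative abundance fraction `tad80 / ge`.
#' @export
relative_abundance <- function(tad80, ge) {
  .check(all(ge > 0), "genome equivalents must be > 0")
  .check(all(tad80 >= 0), "tad80 must be >= 0")
  tad80 / ge
}

#' TAD matrix from simulated or loaded depth profiles
#'
#' @param profile_sim Output of [simulate_depth_profiles()] (or any list
#'   with `profiles[[sample]][[genome]]` depth vectors).
#' @param central_fraction Passed to [tad()].
#' @return Genome x sample matrix of TAD values.
#' @export
tad_matrix <- function(profile_sim, central_fraction = 0.8) {
  samples <- names(profile_sim$profiles)
  genomes <- names(profile_sim$profiles[[1]])
  out <- vapply(samples, function(s)
    vapply(genomes, function(g)
      tad(profile_sim$profiles[[s]][[g]], central_fraction), numeric(1)),
    numeric(length(genomes)))
  matrix(out, nrow = length(genomes), dimnames = list(genomes, samples))
}

#' Relative abundance matrix from depth profiles and sample stats
#'
#' Runs the full profiling chain: TAD per genome and sample, average
#' genome size from marker hits, genome equivalents from sequencing
#' totals, and relative abundance `TAD / GE`. With `use_true_ge = TRUE`
#' the simulation's ground-truth genome equivalents replace the
#' marker-based estimate (the noiseless variant).
#'
#' @param profile_sim Output of [simulate_depth_profiles()].
#' @param central_fraction Passed to [tad()].
#' @param use_true_ge Use ground-truth genome equivalents.
#' @return List with `abundance` (genome x sample fractions), `tad`,
#'   `genome_equivalents`, `avg_genome_size` (both per sample).
#' @export
abundance_matrix <- function(profile_sim, central_fraction = 0.8,
                             use_true_ge = FALSE) {
  td <- tad_matrix(profile_sim, central_fraction)
  st <- profile_sim$sample_stats$stats
  cfg <- profile_sim$config
  if (use_true_ge) {
    ge <- profile_sim$sample_stats$truth$genome_equivalents[colnames(td)]
    ags <- profile_sim$sample_stats$truth$avg_genome_size[colnames(td)]
  } else {
    hit_cols <- grep("^hits_", names(st), value = TRUE)
    calib <- cfg$marker_constants[sub("^hits_", "", hit_cols)]
    ags <- vapply(seq_len(nrow(st)), function(i)
      estimate_avg_genome_size(st$total_bp[i],
                               setNames(as.numeric(st[i, hit_cols]),
                                        names(calib)),
                               calib), numeric(1))
    names(ags) <- st$sample
    ags <- ags[colnames(td)]
    ge <- genome_equivalents(st$total_bp[match(colnames(td), st$sample)], ags)
    names(ge) <- colnames(td)
  }
  ab <- sweep(td, 2, ge, "/")
  list(abundance = ab, tad = td, genome_equivalents = ge,
       avg_genome_size = ags)
}

#' Per-species prevalence and average relative abundance
#'
#' Prevalence is the percentage of samples in which a species is detected
#' (default detection rule: TAD-derived abundance > 0). The average
#' relative abundance is, by default, the mean over detected samples
#' only; set `zeros_included = TRUE` to average over all samples. Species
#' detected nowhere get prevalence 0 and average 0, flagged by
#' `ever_detected = FALSE`.
#'
#' @param abundance Species x sample relative-abundance matrix.
#' @param detection Optional logical detection mask of the same shape;
#'   defaults to `abundance > 0`.
#' @param zeros_included Average over all samples instead of detected
#'   samples only.
#' @return data.frame with `species`, `prevalence` (%), `avg_abundance`
#'   (%), `n_detected`, `ever_detected`.
#' @export
prevalence_and_average <- function(abundance, detection = NULL,
                                   zeros_included = FALSE) {
  .check(ncol(abundance) > 0, "zero samples")
  if (is.null(detection)) detection <- abundance > 0
  n_det <- rowSums(detection)
  avg <- if (zeros_included) rowMeans(abundance)
         else ifelse(n_det > 0, rowSums(abundance * detection) / n_det, 0)
  data.frame(
    species = rownames(abundance),
    prevalence = 100 * n_det / ncol(abundance),
    avg_abundance = 100 * avg,
    n_detected = as.integer(n_det),
    ever_detected = n_det > 0,
    stringsAsFactors = FALSE, row.names = NULL)
}
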