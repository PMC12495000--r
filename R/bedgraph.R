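#' Write a windowed depth vector as BedGraph
#'
#' Emits 4-column BedGraph (`seqname`, `start`, `end`, `depth`; 0-based,
#' half-open) with runs of equal depth merged into single intervals.
#' Interval boundaries fall on window multiples except the final end,
#' which is clipped to the genome length. An all-zero profile is emitted
#' as one zero interval covering the genome.
#'
#' @param depths Integer/numeric per-window depth vector.
#' @param file Output path.
#' @param seqname Contig/genome name for column 1.
#' @param window Window size in bp the depths were computed over.
#' @param genome_length Genome length in bp; defaults to
#'   `length(depths) * window`.
#' @return The output path, invisibly.
#' @export
write_bedgraph <- function(depths, file, seqname = "genome", window = 100L,
                           genome_length = NULL) {
  .check(length(depths) > 0, "empty depth vector")
  if (is.null(genome_length)) genome_length <- length(depths) * window
  r <- rle(as.numeric(depths))
  ends_w <- cumsum(r$lengths)
  starts <- c(0, ends_w[-length(ends_w)]) * window
  ends <- pmin(ends_w * window, genome_length)
  data.table::fwrite(
    data.table::data.table(seqname, as.integer(starts), as.integer(ends),
                           r$values),
    file = file, sep = "\t", col.names = FALSE)
  invisible(file)
}

#' Read a BedGraph file back into a per-window depth vector
#'
#' Inverse of [write_bedgraph()] at the same window size: each interval is
#' expanded to `ceiling((end - start) / window)` windows of its depth, so
#' a write/read round trip reproduces the depth vector exactly.
#'
#' @param file BedGraph path (4 columns, 0-based half-open).
#' @param window Window size in bp.
#' @return Numeric depth vector with attribute `seqname`.
#' @export
read_bedgraph <- function(file, window = 100L) {
  bg <- data.table::fread(file, header = FALSE, sep = "\t",
                          col.names = c("seqname", "start", "end", "depth"))
  .check(nrow(bg) > 0, "empty BedGraph file: %s", file)
  .check(all(bg$end > bg$start), "malformed BedGraph interval in %s", file)
  nw <- ceiling((bg$end - bg$start) / window)
  out <- rep(bg$depth, nw)
  attr(out, "seqname") <- bg$seqname[1]
  out
}

#' Write every genome x sample profile of a simulation as BedGraph
#'
#' One file per genome and sample, named `<sample>/<genome>.bedGraph`,
#' under `dir`, plus a `manifest.tsv` listing them. Zero-abundance
#' species still get an explicit (all-zero) file so prevalence
#' denominators are unambiguous.
#'
#' @param profile_sim Output of [simulate_depth_profiles()].
#' @param dir Output directory (created if needed).
#' @return data.frame manifest (`sample`, `genome`, `path`), invisibly.
#' @export
write_profile_dir <- function(profile_sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in names(profile_sim$profiles)) {
    sdir <- file.path(dir, s)
    dir.create(sdir, showWarnings = FALSE)
    for (g in names(profile_sim$profiles[[s]])) {
      path <- file.path(sdir, paste0(g, ".bedGraph"))
      write_bedgraph(profile_sim$profiles[[s]][[g]], path, seqname = g,
                     window = profile_sim$window)
      rows[[length(rows) + 1L]] <- data.frame(sample = s, genome = g,
                                              path = path,
                                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  data.table::fwrite(manifest, file.path(dir, "manifest.tsv"), sep = "\t")
  invisible(manifest)
}
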