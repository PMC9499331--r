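#' Chromosome lengths of a map specification
#'
#' @param spec a `map_spec`.
#' @return Named numeric vector of physical lengths (bp).
#' @export
chrom_lengths <- function(spec) {
  stats::setNames(spec$chromosomes$length_bp, spec$chromosomes$name)
}

#' Run the bin-map pipeline from a marker matrix
#'
#' Convenience wrapper: sliding-window genotype scan, bin partition,
#' segregation filter, and map construction (fixed order, rippling,
#' correction/merging).
#'
#' @param mm a `marker_matrix`.
#' @param params a [window_params()].
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param chi2_max segregation filter threshold.
#' @param ... passed to [build_map()].
#' @return list `map`, `bins`, `windows`, `n_corrections`, `n_merged`.
#' @export
bin_map_pipeline <- function(mm, params = window_params(),
                             chrom_lengths = NULL, chi2_max = 25, ...) {
  wt <- window_scan(mm, params, chrom_lengths)
  bs <- partition_bins(wt, chi2_max = chi2_max)
  built <- build_map(bs, ...)
  c(built, list(windows = wt))
}

#' Read and write phenotype tables
#'
#' Tab-separated with columns `line_id`, `trait`, `season`, `value`.
#'
#' @param path file path.
#' @return [read_phenotype_tsv()] returns the phenotype data frame.
#' @export
read_phenotype_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}

#' @rdname read_phenotype_tsv
#' @param phenotypes phenotype data frame.
#' @export
write_phenotype_tsv <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write a simulated study to disk
#'
#' Emits the marker TSV, phenotype TSV and a truth JSON (map spec
#' dimensions, QTL, crossover counts and any mis-assembly record) so a
#' simulated dataset can be re-analyzed from files alone.
#'
#' @param mm observed `marker_matrix`.
#' @param f2 the generating `f2_sim`.
#' @param dir output directory.
#' @param phenotypes optional phenotype data frame.
#' @param qtl optional `qtl_spec` used for the phenotypes.
#' @param misassembly_truth optional truth record from
#'   [simulate_misassembly()].
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(mm, f2, dir, phenotypes = NULL, qtl = NULL,
                             misassembly_truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "markers.tsv")
  write_marker_tsv(mm, paths)
  truth <- list(
    chromosomes = f2$spec$chromosomes,
    n_individuals = length(f2$individuals),
    crossovers = lapply(f2$meioses, function(ch)
      lapply(ch, function(ind) ind$xo)))
  if (!is.null(qtl)) truth$qtl <- unclass(qtl)
  if (!is.null(misassembly_truth)) truth$misassembly <- misassembly_truth
  pt <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, pt, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, pt)
  if (!is.null(phenotypes)) {
    pp <- file.path(dir, "phenotypes.tsv")
    write_phenotype_tsv(phenotypes, pp)
    paths <- c(paths, pp)
  }
  invisible(paths)
}
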