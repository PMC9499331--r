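#' Construct a marker genotype matrix
#'
#' The pipeline's working container: markers (rows, sorted by chromosome
#' then position) by individuals (columns), with genotype codes
#' 0 (parent-A homozygote), 1 (heterozygote), 2 (parent-B homozygote) and
#' `NA` for missing.
#'
#' @param geno integer matrix of codes 0/1/2/NA, markers x individuals.
#' @param chrom character vector of chromosome names, one per marker.
#' @param pos integer vector of physical positions (bp, 1-based).
#' @param parents optional named character vector `c(A = ..., B = ...)`
#'   recording which parent anchors code 0.
#' @return An object of class `marker_matrix`.
#' @export
marker_matrix <- function(geno, chrom, pos, parents = NULL) {
  stopifnot(is.matrix(geno), length(chrom) == nrow(geno),
            length(pos) == nrow(geno), all(pos >= 1))
  bad <- !is.na(geno) & !(geno %in% 0:2)
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  o <- order(chrom, pos)
  structure(list(geno = geno[o, , drop = FALSE],
                 chrom = as.character(chrom)[o],
                 pos = as.integer(pos)[o],
                 parents = parents),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("marker_matrix:", nrow(x$geno), "markers x", ncol(x$geno),
      "individuals on", length(unique(x$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$geno)

#' Probability that a heterozygote is miscalled homozygous at depth k
#'
#' With k reads drawn independently and uniformly from the two alleles, a
#' heterozygote shows only one allele -- and is therefore called
#' homozygous -- with probability 2 (1/2)^k = 1/2^(k-1). One read can never
#' reveal both alleles, so the probability is 1 at k = 1, 1/2 at the ~2x
#' depth typical of low-coverage resequencing, and below 1/16 once depth
#' exceeds 5.
#'
#' @param k integer sequencing depth(s), `k >= 1`.
#' @return Miscall probability, same length as `k`.
#' @export
het_miscall_prob <- function(k) {
  if (any(k < 1) || any(k != as.integer(k))) stop("k must be integer >= 1")
  1 / 2^(k - 1)
}

#' Select markers from parental and F2 variant calls
#'
#' Applies the selection criteria for a biparental F2 marker set:
#' (1) diallelic; (2) parent A homozygous (and, to anchor codes 0 and 2
#' unambiguously, parent B homozygous for the other allele); (3) minor
#' allele frequency in the F2 at least `maf_min`, computed from allele
#' counts over non-missing genotypes. Retained genotypes are recoded with
#' parent A's allele as 0.
#'
#' @param variants a `variant_table` as from [read_variant_tsv()] or
#'   [read_variant_vcf()]: list with `chrom`, `pos`, `ref`, `alt`
#'   (comma-separated for multiallelic sites) and `geno`, a character
#'   matrix of diploid genotypes in allele-index form (`"0/0"`, `"0/1"`,
#'   `"1/1"`, `"./."`), one column per sample.
#' @param parent_a,parent_b sample names of the two parents.
#' @param maf_min minimum F2 minor allele frequency (default 0.3).
#' @return A `marker_matrix` of the selected, recoded markers; attribute
#'   `"excluded"` tabulates exclusion reasons.
#' @export
select_markers <- function(variants, parent_a, parent_b, maf_min = 0.3) {
  g <- variants$geno
  if (!parent_a %in% colnames(g)) stop("parent sample missing: ", parent_a)
  if (!parent_b %in% colnames(g)) stop("parent sample missing: ", parent_b)
  f2_cols <- setdiff(colnames(g), c(parent_a, parent_b))
  parse_gt <- function(s) {
    a <- sub("[/|].*", "", s); b <- sub(".*[/|]", "", s)
    a[a == "."] <- NA; b[b == "."] <- NA
    cbind(as.integer(a), as.integer(b))
  }
  n_alt <- lengths(strsplit(variants$alt, ",", fixed = TRUE))
  diallelic <- n_alt == 1L
  pa <- parse_gt(g[, parent_a]); pb <- parse_gt(g[, parent_b])
  a_hom <- !is.na(pa[, 1]) & !is.na(pa[, 2]) & pa[, 1] == pa[, 2]
  b_hom <- !is.na(pb[, 1]) & !is.na(pb[, 2]) & pb[, 1] == pb[, 2]
  polym <- a_hom & b_hom & pa[, 1] != pb[, 1]
  cand <- diallelic & polym
  ## recode F2 genotypes relative to parent A's allele
  codes <- matrix(NA_integer_, nrow(g), length(f2_cols),
                  dimnames = list(NULL, f2_cols))
  for (j in seq_along(f2_cols)) {
    ff <- parse_gt(g[, f2_cols[j]])
    codes[, j] <- (ff[, 1] != pa[, 1]) + (ff[, 2] != pa[, 1])
  }
  nn <- rowSums(!is.na(codes))
  n0 <- rowSums(codes == 0L, na.rm = TRUE)
  n1 <- rowSums(codes == 1L, na.rm = TRUE)
  fA <- ifelse(nn > 0, (2 * n0 + n1) / (2 * nn), NA)
  maf <- pmin(fA, 1 - fA)
  keep <- cand & !is.na(maf) & maf >= maf_min
  excluded <- c(not_diallelic = sum(!diallelic),
                parent_not_informative = sum(diallelic & !polym),
                low_maf = sum(cand & (is.na(maf) | maf < maf_min)))
  mm <- marker_matrix(codes[keep, , drop = FALSE],
                      variants$chrom[keep], variants$pos[keep],
                      parents = c(A = parent_a, B = parent_b))
  attr(mm, "excluded") <- excluded
  mm
}

#' Per-marker summary statistics
#'
#' MAF is computed from allele counts, (2 n0 + n1) / (2 n), over
#' non-missing genotypes; missing genotypes are excluded, never imputed.
#'
#' @param mm a `marker_matrix`.
#' @return data frame `chrom`, `pos`, `n`, `maf`, `missing`.
#' @export
compute_marker_stats <- function(mm) {
  g <- mm$geno
  if (!nrow(g)) stop("empty marker matrix")
  nn <- rowSums(!is.na(g))
  n0 <- rowSums(g == 0L, na.rm = TRUE)
  n1 <- rowSums(g == 1L, na.rm = TRUE)
  fA <- ifelse(nn > 0, (2 * n0 + n1) / (2 * nn), NA)
  data.frame(chrom = mm$chrom, pos = mm$pos, n = nn,
             maf = pmin(fA, 1 - fA),
             missing = 1 - nn / ncol(g))
}

#' Per-individual quality control
#'
#' Reports each individual's observed proportion of heterozygous genotype
#' calls (PHG) and missing fraction. When a nominal sequencing depth is
#' supplied, the expected PHG under the read-sampling model is attached:
#' a true F2 heterozygote proportion pe = 0.5 is observed as
#' po = pe (1 - pm) with pm = 1/2^(k-1), e.g. po = 0.25 at depth 2.
#'
#' @param mm a `marker_matrix`.
#' @param depth_k optional nominal per-marker sequencing depth.
#' @return data frame `individual`, `n`, `phg`, `missing`, `flagged`
#'   (all genotypes missing); attributes `pm` and `expected_phg` when
#'   `depth_k` is given.
#' @export
compute_individual_qc <- function(mm, depth_k = NULL) {
  g <- mm$geno
  nn <- colSums(!is.na(g))
  phg <- ifelse(nn > 0, colSums(g == 1L, na.rm = TRUE) / nn, NA)
  out <- data.frame(individual = colnames(g), n = nn, phg = phg,
                    missing = 1 - nn / nrow(g), flagged = nn == 0,
                    row.names = NULL)
  if (!is.null(depth_k)) {
    pm <- het_miscall_prob(depth_k)
    attr(out, "pm") <- pm
    attr(out, "expected_phg") <- 0.5 * (1 - pm)
  }
  out
}

#' Genomic relatedness of F2 individuals
#'
#' Centered-and-scaled allele-dosage genomic relationship matrix
#' (VanRaden's first method): with dosage matrix Z centered by twice the
#' allele frequency, G = Z'Z / (2 sum p(1-p)). Missing dosages are replaced
#' by the marker mean for this computation only. Off-diagonal coefficients
#' are standardized to z-scores ("relatedness scores"); in a well-behaved
#' F2 these are approximately normal.
#'
#' @param mm a `marker_matrix` with at least 3 individuals.
#' @return list with `grm` (symmetric matrix), `scores` (data frame of
#'   off-diagonal pairs and standardized coefficients).
#' @export
relatedness_scores <- function(mm) {
  g <- mm$geno
  if (ncol(g) < 3) stop("need at least 3 individuals")
  p <- rowMeans(g, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  if (!any(keep)) stop("no polymorphic markers with data")
  g <- g[keep, , drop = FALSE]; p <- p[keep]
  z <- g - 2 * p
  z[is.na(z)] <- 0  # mean-impute: centered missing dosage contributes 0
  grm <- crossprod(z) / (2 * sum(p * (1 - p)))
  ut <- upper.tri(grm)
  v <- grm[ut]
  if (stats::sd(v) == 0) stop("zero variance among relationship coefficients")
  idx <- which(ut, arr.ind = TRUE)
  scores <- data.frame(ind1 = colnames(g)[idx[, 1]],
                       ind2 = colnames(g)[idx[, 2]],
                       coefficient = v,
                       score = (v - mean(v)) / stats::sd(v))
  list(grm = grm, scores = scores)
}

#' Read and write the marker TSV dialect
#'
#' Plain tab-separated table with columns `chrom`, `pos` and one column of
#' codes 0/1/2/NA per individual.
#'
#' @param path file path.
#' @return [read_marker_tsv()] returns a `marker_matrix`.
#' @export
read_marker_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  geno <- as.matrix(d[, setdiff(names(d), c("chrom", "pos")), drop = FALSE])
  storage.mode(geno) <- "integer"
  marker_matrix(geno, d$chrom, d$pos)
}

#' @rdname read_marker_tsv
#' @param mm a `marker_matrix`.
#' @export
write_marker_tsv <- function(mm, path) {
  d <- data.frame(chrom = mm$chrom, pos = mm$pos, check.names = FALSE)
  d <- cbind(d, as.data.frame(mm$geno))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read variants from a TSV dialect
#'
#' Columns `chrom pos ref alt` followed by one genotype column per sample
#' in allele-index form (`0/0`, `0/1`, `1/1`, `./.`).
#'
#' @param path file path.
#' @return A `variant_table` suitable for [select_markers()].
#' @export
read_variant_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         colClasses = "character")
  samples <- setdiff(names(d), c("chrom", "pos", "ref", "alt"))
  structure(list(chrom = d$chrom, pos = as.integer(d$pos),
                 ref = d$ref, alt = d$alt,
                 geno = as.matrix(d[, samples, drop = FALSE])),
            class = "variant_table")
}

#' Read variants from a VCF file
#'
#' Thin wrapper over `vcfR::read.vcfR()` extracting chromosome, position,
#' alleles and per-sample GT fields.
#'
#' @param path VCF file path.
#' @return A `variant_table` suitable for [select_markers()].
#' @export
read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt[is.na(gt)] <- "./."
  structure(list(chrom = as.character(v@fix[, "CHROM"]),
                 pos = as.integer(v@fix[, "POS"]),
                 ref = as.character(v@fix[, "REF"]),
                 alt = as.character(v@fix[, "ALT"]),
                 geno = gt),
            class = "variant_table")
}
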