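#' Partition window tracks into recombination bins
#'
#' A recombination bin is a maximal run of consecutive anchors whose window
#' genotype vectors completely co-segregate across the population. Matching
#' is NA-tolerant: an anchor joins the current run when every individual's
#' non-missing call agrees with the run's consensus (a consensus `NA` is
#' filled by the first non-missing call encountered). Every anchor belongs
#' to exactly one bin; bins inherit the physical extent
#' `[first_anchor - step/2, last_anchor + step/2)`, so bin lengths are
#' multiples of the step (minimum one step).
#'
#' Bins are named `B<chrom>_<ordinal>`; the chromosome part keeps the
#' digits of the chromosome name when present.
#'
#' @param wt a `window_tracks` from [window_scan()].
#' @param chi2_max segregation chi-square threshold; bins exceeding it are
#'   flagged as dropped (see [segregation_chi2()]). Use `Inf` to keep all.
#' @return An object of class `bin_set`: `bins` data frame (`bin_id`,
#'   `chrom`, `start`, `end`, `anchor_first`, `anchor_last`, `n_anchors`,
#'   `n0`, `n1`, `n2`, `chi2`, `kept`) and `geno`, the bins x individuals
#'   consensus genotype matrix.
#' @export
partition_bins <- function(wt, chi2_max = 25) {
  step <- wt$params$step
  all_bins <- list(); all_geno <- list()
  for (nm in names(wt$tracks)) {
    t <- wt$tracks[[nm]]
    calls <- t$call
    n_anchor <- nrow(calls)
    if (!n_anchor) next
    starts <- integer(0); ends <- integer(0)
    cons_list <- list()
    cons <- calls[1, ]
    run_start <- 1L
    if (n_anchor > 1) for (a in 2:n_anchor) {
      v <- calls[a, ]
      ok <- is.na(v) | is.na(cons) | v == cons
      if (all(ok)) {
        fill <- is.na(cons) & !is.na(v)
        cons[fill] <- v[fill]
      } else {
        starts <- c(starts, run_start); ends <- c(ends, a - 1L)
        cons_list[[length(cons_list) + 1L]] <- cons
        cons <- v; run_start <- a
      }
    }
    starts <- c(starts, run_start); ends <- c(ends, n_anchor)
    cons_list[[length(cons_list) + 1L]] <- cons
    digits <- gsub("\\D", "", nm)
    tag <- if (nzchar(digits)) sprintf("%02d", as.integer(digits)) else nm
    ids <- sprintf("B%s_%d", tag, seq_along(starts))
    geno <- do.call(rbind, cons_list)
    rownames(geno) <- ids
    all_bins[[nm]] <- data.frame(
      bin_id = ids, chrom = nm,
      start = t$anchors[starts] - step / 2,
      end = t$anchors[ends] + step / 2,
      anchor_first = t$anchors[starts],
      anchor_last = t$anchors[ends],
      n_anchors = ends - starts + 1L)
    all_geno[[nm]] <- geno
  }
  bins <- do.call(rbind, all_bins)
  rownames(bins) <- NULL
  geno <- do.call(rbind, all_geno)
  has_data <- rowSums(!is.na(geno)) > 0
  chi <- data.frame(n0 = 0L, n1 = 0L, n2 = 0L, chi2 = NA_real_, kept = FALSE,
                    row.names = NULL)[rep(1, nrow(geno)), ]
  if (any(has_data))
    chi[has_data, ] <- segregation_chi2(geno[has_data, , drop = FALSE],
                                        chi2_max = chi2_max)
  bins <- cbind(bins, chi[, c("n0", "n1", "n2", "chi2", "kept")])
  rownames(bins) <- NULL
  structure(list(bins = bins, geno = geno, params = wt$params),
            class = "bin_set")
}

#' @export
print.bin_set <- function(x, ...) {
  cat("bin_set:", nrow(x$bins), "bins on",
      length(unique(x$bins$chrom)), "chromosome(s);",
      sum(!x$bins$kept), "flagged by the segregation filter\n")
  invisible(x)
}

#' Chi-square test of 1:2:1 segregation per bin
#'
#' Pearson chi-square of observed genotype counts against the Mendelian
#' F2 expectation (1/4, 1/2, 1/4) on 2 df. Bins with chi-square above
#' `chi2_max` (default 25, i.e. p < 1e-5) show serious segregation
#' distortion and are flagged for removal.
#'
#' @param geno bins x individuals genotype matrix (or a single bin's
#'   genotype vector).
#' @param chi2_max drop threshold.
#' @return data frame `n0`, `n1`, `n2`, `chi2`, `kept`.
#' @export
segregation_chi2 <- function(geno, chi2_max = 25) {
  if (is.vector(geno)) geno <- matrix(geno, nrow = 1)
  n0 <- rowSums(geno == 0L, na.rm = TRUE)
  n1 <- rowSums(geno == 1L, na.rm = TRUE)
  n2 <- rowSums(geno == 2L, na.rm = TRUE)
  n <- n0 + n1 + n2
  if (any(n == 0)) stop("bin with no non-missing genotypes")
  e0 <- n / 4; e1 <- n / 2
  chi2 <- (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e0)^2 / e0
  data.frame(n0 = n0, n1 = n1, n2 = n2, chi2 = chi2, kept = chi2 <= chi2_max)
}

#' Drop bins flagged by the segregation filter
#'
#' @param bs a `bin_set`.
#' @return A `bin_set` restricted to kept bins.
#' @export
filter_bins <- function(bs) {
  keep <- bs$bins$kept
  structure(list(bins = bs$bins[keep, , drop = FALSE],
                 geno = bs$geno[keep, , drop = FALSE],
                 params = bs$params),
            class = "bin_set")
}

#' Detect genotype transitions along one individual's window track
#'
#' Lists ordered transitions between consecutive defined calls, skipping
#' runs of `NA`. A direct 0 <-> 2 transition implies two crossovers inside
#' the gap and is flagged.
#'
#' @param anchors anchor positions (bp).
#' @param calls integer window calls 0/1/2/NA at the anchors.
#' @return data frame `anchor_before`, `anchor_after`, `from_call`,
#'   `to_call`, `double_event`.
#' @export
detect_breakpoints <- function(anchors, calls) {
  def <- which(!is.na(calls))
  out <- data.frame(anchor_before = numeric(0), anchor_after = numeric(0),
                    from_call = integer(0), to_call = integer(0),
                    double_event = logical(0))
  if (length(def) < 2) return(out)
  v <- calls[def]
  ch <- which(diff(v) != 0)
  if (!length(ch)) return(out)
  data.frame(anchor_before = anchors[def[ch]],
             anchor_after = anchors[def[ch + 1]],
             from_call = v[ch], to_call = v[ch + 1],
             double_event = abs(diff(v))[ch] == 2L)
}

#' Export a bin set as BED-like tables
#'
#' @param bs a `bin_set`.
#' @param dir output directory; writes `bins.tsv` and `bin_genotypes.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_bin_set <- function(bs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "bins.tsv")
  p2 <- file.path(dir, "bin_genotypes.tsv")
  utils::write.table(bs$bins, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- data.frame(bin_id = rownames(bs$geno), bs$geno, check.names = FALSE)
  utils::write.table(g, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
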