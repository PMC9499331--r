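#' Sliding-window parameters for genotype-index calling
#'
#' Defaults follow the low-depth F2 calling scheme: a fixed 300 kb window
#' sliding in 10 kb steps, requiring at least 10 (non-missing) markers per
#' window, with genotype-index thresholds 0.2 and 1.8.
#'
#' @param window_size window size in bp.
#' @param step step length in bp.
#' @param min_markers minimum non-missing markers for a valid GI.
#' @param low_threshold GI at or below which the call is 0.
#' @param high_threshold GI above which the call is 2.
#' @return An object of class `window_params`.
#' @export
window_params <- function(window_size = 3e5, step = 1e4, min_markers = 10,
                          low_threshold = 0.2, high_threshold = 1.8) {
  stopifnot(step > 0, window_size >= step,
            low_threshold > 0, high_threshold > low_threshold,
            high_threshold < 2)
  structure(list(window_size = window_size, step = step,
                 min_markers = min_markers,
                 low_threshold = low_threshold,
                 high_threshold = high_threshold),
            class = "window_params")
}

#' Genotype index of a set of marker codes
#'
#' GI = 0 p0 + 1 p1 + 2 p2 where p0, p1, p2 are the proportions of codes
#' 0, 1, 2 among the non-missing markers in a window. GI lies in [0, 2]:
#' near 0 in a parent-A region, near 2 in a parent-B region, and -- because
#' a low-depth heterozygote is miscalled towards either homozygote with
#' equal probability -- near 1 in a heterozygous region, where the
#' per-marker errors average out.
#'
#' @param codes integer codes 0/1/2/NA.
#' @param min_markers minimum non-missing codes; fewer yields `NA`.
#' @return GI value, or `NA` when the window is unreliable.
#' @export
genotype_index <- function(codes, min_markers = 10) {
  codes <- codes[!is.na(codes)]
  if (length(codes) < min_markers) return(NA_real_)
  mean(codes)
}

#' Discretize a genotype index into a window genotype call
#'
#' Boundary semantics: call 0 when GI <= low, 1 when low < GI <= high,
#' 2 when GI > high.
#'
#' @param gi genotype index values (in [0, 2] or `NA`).
#' @param params a [window_params()].
#' @return Integer calls 0/1/2 (`NA` preserved).
#' @export
discretize_gi <- function(gi, params = window_params()) {
  if (any(gi < 0 | gi > 2, na.rm = TRUE)) stop("GI must lie in [0, 2]")
  out <- ifelse(gi <= params$low_threshold, 0L,
                ifelse(gi <= params$high_threshold, 1L, 2L))
  as.integer(out)
}

#' Sliding-window genotype scan of a marker matrix
#'
#' For every individual and chromosome, computes the genotype index in a
#' window of `window_size` bp centered on each anchor of a regular `step`
#' grid, then discretizes it. Windows are half-open
#' `[anchor - window/2, anchor + window/2)` and truncated at chromosome
#' ends; anchors sit at multiples of `step` from `step` up to the
#' chromosome length (so their number is `floor(length/step)`). Anchors
#' with fewer than `min_markers` non-missing markers are `NA`.
#'
#' @param mm a `marker_matrix` (markers sorted by position).
#' @param params a [window_params()].
#' @param chrom_lengths optional named vector of chromosome lengths (bp);
#'   defaults to the last marker position per chromosome.
#' @return An object of class `window_tracks`: per-chromosome list with
#'   `anchors`, `gi` (anchors x individuals) and `call` matrices.
#' @export
window_scan <- function(mm, params = window_params(), chrom_lengths = NULL) {
  out <- list()
  half <- params$window_size / 2
  for (nm in unique(mm$chrom)) {
    idx <- which(mm$chrom == nm)
    pos <- mm$pos[idx]
    if (is.unsorted(pos)) stop("markers not sorted on chromosome ", nm)
    g <- mm$geno[idx, , drop = FALSE]
    L <- if (!is.null(chrom_lengths) && nm %in% names(chrom_lengths))
      chrom_lengths[[nm]] else max(pos)
    anchors <- seq(params$step, L, by = params$step)
    ## cumulative per-code counts down the chromosome, per individual
    c0 <- apply(g == 0L & !is.na(g), 2, cumsum)
    c1 <- apply(g == 1L & !is.na(g), 2, cumsum)
    c2 <- apply(g == 2L & !is.na(g), 2, cumsum)
    zero <- matrix(0, 1, ncol(g))
    c0 <- rbind(zero, c0); c1 <- rbind(zero, c1); c2 <- rbind(zero, c2)
    lo <- findInterval(anchors - half - 0.5, pos) + 1L  # first marker >= lo
    hi <- findInterval(anchors + half - 0.5, pos)       # last marker < hi
    n0 <- c0[hi + 1L, , drop = FALSE] - c0[lo, , drop = FALSE]
    n1 <- c1[hi + 1L, , drop = FALSE] - c1[lo, , drop = FALSE]
    n2 <- c2[hi + 1L, , drop = FALSE] - c2[lo, , drop = FALSE]
    nn <- n0 + n1 + n2
    gi <- (n1 + 2 * n2) / nn
    gi[nn < params$min_markers] <- NA_real_
    call <- matrix(discretize_gi(gi, params), nrow(gi), ncol(gi))
    dimnames(gi) <- dimnames(call) <- list(NULL, colnames(mm$geno))
    out[[nm]] <- list(anchors = anchors, gi = gi, call = call)
  }
  structure(list(tracks = out, params = params), class = "window_tracks")
}

#' @export
print.window_tracks <- function(x, ...) {
  for (nm in names(x$tracks))
    cat(nm, ":", length(x$tracks[[nm]]$anchors), "anchors x",
        ncol(x$tracks[[nm]]$call), "individuals\n")
  invisible(x)
}

#' Export window calls as a long table
#'
#' @param wt a `window_tracks`.
#' @return data frame `chrom`, `anchor`, `individual`, `gi`, `call`.
#' @export
window_tracks_long <- function(wt) {
  do.call(rbind, lapply(names(wt$tracks), function(nm) {
    t <- wt$tracks[[nm]]
    data.frame(chrom = nm,
               anchor = rep(t$anchors, ncol(t$gi)),
               individual = rep(colnames(t$gi), each = length(t$anchors)),
               gi = as.vector(t$gi),
               call = as.vector(t$call))
  }))
}
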