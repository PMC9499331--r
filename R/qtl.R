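## F2 genotype transition matrix between two loci at recombination
## fraction r: rows = genotype at the left locus, columns = right locus
.geno_trans <- function(r) {
  matrix(c((1 - r)^2,     2 * r * (1 - r),       r^2,
           r * (1 - r),   (1 - r)^2 + r^2,       r * (1 - r),
           r^2,           2 * r * (1 - r),       (1 - r)^2),
         3, 3, byrow = TRUE)
}

## expected additive (x in {-1,0,1}) and F2:3 dominance (z in {0, 1/2})
## codings at scan positions, from flanking bin genotypes.
## Returns, per LG, positions plus an x and z matrix (positions x lines).
.scan_designs <- function(map, bs, lines, step_cm = 1, map_fun = "kosambi") {
  tab <- map$table
  prior <- c(0.25, 0.5, 0.25)
  designs <- list()
  for (lg in unique(tab$lg)) {
    g <- tab[tab$lg == lg, ]
    geno <- bs$geno[g$bin_id, lines, drop = FALSE]
    len <- max(g$cm)
    pos <- unique(sort(c(seq(0, len, by = step_cm), len, g$cm)))
    X <- matrix(NA_real_, length(pos), length(lines))
    Z <- matrix(NA_real_, length(pos), length(lines))
    lb <- character(length(pos)); rb <- character(length(pos))
    for (k in seq_along(pos)) {
      p <- pos[k]
      il <- max(which(g$cm <= p + 1e-9))
      ir <- min(which(g$cm >= p - 1e-9))
      lb[k] <- g$bin_id[il]; rb[k] <- g$bin_id[ir]
      rl <- map_rf(max(p - g$cm[il], 0), map_fun)
      rr <- map_rf(max(g$cm[ir] - p, 0), map_fun)
      Tl <- .geno_trans(rl); Tr <- .geno_trans(rr)
      rt <- rl * (1 - rr) + rr * (1 - rl)
      Tt <- .geno_trans(rt)
      ## probability triple for each (gL, gR) combination incl. missing (4th)
      lut_x <- matrix(NA_real_, 4, 4); lut_z <- matrix(NA_real_, 4, 4)
      for (a in 1:4) for (b in 1:4) {
        pq <- if (a < 4 && b < 4) {
          v <- Tl[a, ] * Tr[, b] / max(Tt[a, b], 1e-300)
          v / sum(v)
        } else if (a < 4) {
          Tl[a, ]
        } else if (b < 4) {
          v <- prior * Tr[, b]; v / sum(v)
        } else prior
        lut_x[a, b] <- pq[3] - pq[1]
        lut_z[a, b] <- 0.5 * pq[2]
      }
      ia <- geno[il, ] + 1L; ia[is.na(ia)] <- 4L
      ib <- geno[ir, ] + 1L; ib[is.na(ib)] <- 4L
      X[k, ] <- lut_x[cbind(ia, ib)]
      Z[k, ] <- lut_z[cbind(ia, ib)]
    }
    designs[[lg]] <- list(lg = lg, pos = pos, X = X, Z = Z,
                          left_bin = lb, right_bin = rb)
  }
  designs
}

## LOD, effects and PVE of y on one (x, z) design
.hk_fit <- function(x, z, y) {
  n <- length(y)
  X <- cbind(1, x, z)
  fit <- stats::lm.fit(X, y)
  co <- fit$coefficients; co[is.na(co)] <- 0
  rss1 <- sum(fit$residuals^2)
  rss0 <- sum((y - mean(y))^2)
  lod <- if (rss0 <= 0 || rss1 <= 0) 0 else max(n / 2 * log10(rss0 / rss1), 0)
  c(lod = lod, add = co[2], dom = co[3],
    pve = if (rss0 > 0) 100 * (1 - rss1 / rss0) else 0)
}

#' Haley-Knott interval mapping on a bin map
#'
#' At each position of a cM grid along every linkage group, the F2 QTL
#' genotype distribution is inferred from the flanking bin genotypes via
#' the mapping function, and the line means are regressed on the expected
#' additive coding x (in \{-1, 0, +1\}) and the F2:3 dominance coding z
#' (1/2 for a heterozygous F2 parent, whose F3 family mean carries half the
#' dominance deviation). LOD = (n/2) log10(RSS0/RSS1); the additive and
#' dominance effects are the regression coefficients, and PVE (%) is
#' 100 (1 - RSS1/RSS0).
#'
#' A negative additive effect means the parent-B (code 2) allele decreases
#' the trait.
#'
#' @param map a `genetic_map`.
#' @param bs the matching `bin_set`.
#' @param phenotypes data frame `line_id`, `value` (plus optional `trait`,
#'   `season` carried through); line ids must match genotype columns.
#' @param step_cm scan grid spacing (cM).
#' @return An object of class `lod_curve`: data frame `lg`, `cm`, `lod`,
#'   `add`, `dom`, `pve`, `left_bin`, `right_bin`.
#' @export
interval_mapping_scan <- function(map, bs, phenotypes, step_cm = 1) {
  ph <- phenotypes[!is.na(phenotypes$value), ]
  lines <- intersect(colnames(bs$geno), ph$line_id)
  if (length(lines) < 30) stop("need at least 30 phenotyped lines")
  y <- ph$value[match(lines, ph$line_id)]
  designs <- .scan_designs(map, bs, lines, step_cm, map$map_fun)
  out <- lapply(designs, function(d) {
    res <- t(vapply(seq_along(d$pos), function(k)
      .hk_fit(d$X[k, ], d$Z[k, ], y), numeric(4)))
    data.frame(lg = d$lg, cm = d$pos, lod = res[, 1], add = res[, 2],
               dom = res[, 3], pve = res[, 4],
               left_bin = d$left_bin, right_bin = d$right_bin)
  })
  curve <- do.call(rbind, out)
  rownames(curve) <- NULL
  class(curve) <- c("lod_curve", "data.frame")
  attr(curve, "n_lines") <- length(lines)
  curve
}

#' Genome-wide LOD threshold by phenotype permutation
#'
#' The phenotype vector is permuted against the genotypes `n_perm` times;
#' each permutation is scanned over the whole map and its maximum LOD
#' recorded. The threshold is the (1 - alpha) quantile of these maxima.
#'
#' @inheritParams interval_mapping_scan
#' @param n_perm number of permutations (1000 for a production run).
#' @param alpha genome-wise significance level.
#' @param seed integer seed for the permutations.
#' @return The LOD threshold (numeric); attribute `"max_lods"` holds the
#'   permutation maxima.
#' @export
permutation_threshold <- function(map, bs, phenotypes, n_perm = 1000,
                                  alpha = 0.05, seed, step_cm = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  set.seed(seed)
  ph <- phenotypes[!is.na(phenotypes$value), ]
  lines <- intersect(colnames(bs$geno), ph$line_id)
  y <- ph$value[match(lines, ph$line_id)]
  n <- length(y)
  designs <- .scan_designs(map, bs, lines, step_cm, map$map_fun)
  Y <- vapply(seq_len(n_perm), function(i) sample(y), numeric(n))
  yss <- sum(y^2)
  rss0 <- yss - n * mean(y)^2
  max_lod <- rep(0, n_perm)
  for (d in designs) {
    for (k in seq_along(d$pos)) {
      X <- cbind(1, d$X[k, ], d$Z[k, ])
      Q <- qr.Q(qr(X))
      rss1 <- pmax(yss - colSums(crossprod(Q, Y)^2), 1e-12)
      lod <- n / 2 * log10(rss0 / rss1)
      max_lod <- pmax(max_lod, lod)
    }
  }
  thr <- if (alpha >= 1) 0 else
    as.numeric(stats::quantile(max_lod, 1 - alpha))
  attr(thr, "max_lods") <- max_lod
  thr
}

#' Call QTL peaks on a LOD curve
#'
#' Local maxima with LOD at or above the threshold, separated by at least
#' `min_sep_cm` within a linkage group (the strongest peak wins). The
#' reported bin interval consists of the mapped bins flanking the peak
#' position; its physical interval runs from the left bin's start to the
#' right bin's end.
#'
#' @param curve a `lod_curve`.
#' @param tlod LOD threshold (e.g. from [permutation_threshold()]).
#' @param map the `genetic_map` used for the scan (for bin coordinates).
#' @param min_sep_cm minimum separation between reported peaks.
#' @return data frame of peaks: `lg`, `pos_cm`, `left_bin`, `right_bin`,
#'   `interval_cm`, `interval_kb`, `width_cm`, `width_kb`, `lod`, `tlod`,
#'   `add`, `dom`, `pve`.
#' @export
call_peaks <- function(curve, tlod, map, min_sep_cm = 20) {
  out <- list()
  for (lg in unique(curve$lg)) {
    cc <- curve[curve$lg == lg, ]
    cand <- which(cc$lod >= tlod)
    if (!length(cand)) next
    cand <- cand[order(-cc$lod[cand])]
    taken <- numeric(0)
    for (k in cand) {
      if (length(taken) && any(abs(cc$cm[k] - taken) < min_sep_cm)) next
      taken <- c(taken, cc$cm[k])
      tb <- map$table
      lb <- cc$left_bin[k]; rb <- cc$right_bin[k]
      il <- match(lb, tb$bin_id); ir <- match(rb, tb$bin_id)
      out[[length(out) + 1L]] <- data.frame(
        lg = lg, pos_cm = cc$cm[k], left_bin = lb, right_bin = rb,
        interval_cm = sprintf("%.2f-%.2f", tb$cm[il], tb$cm[ir]),
        interval_kb = sprintf("%.0f-%.0f", tb$phys_start[il] / 1e3,
                              tb$phys_end[ir] / 1e3),
        width_cm = tb$cm[ir] - tb$cm[il],
        width_kb = (tb$phys_end[ir] - tb$phys_start[il]) / 1e3,
        lod = cc$lod[k], tlod = tlod,
        add = cc$add[k], dom = cc$dom[k], pve = cc$pve[k])
    }
  }
  if (!length(out))
    return(data.frame(lg = character(0), pos_cm = numeric(0),
                      left_bin = character(0), right_bin = character(0),
                      interval_cm = character(0), interval_kb = character(0),
                      width_cm = numeric(0), width_kb = numeric(0),
                      lod = numeric(0), tlod = numeric(0),
                      add = numeric(0), dom = numeric(0), pve = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$lg, res$pos_cm), ]
}

#' Combine QTL estimates across seasons
#'
#' Peaks detected in the same trait, linkage group and bin interval in two
#' or more seasons are combined by arithmetic averaging of the additive
#' effect, dominance effect and PVE.
#'
#' @param peaks data frame of peaks carrying `trait` and `season` columns
#'   in addition to the [call_peaks()] columns.
#' @return The input with combined rows (season `"combined"`) appended for
#'   every multi-season QTL; single-season QTLs pass through unchanged.
#' @export
combine_seasons <- function(peaks) {
  key <- paste(peaks$trait, peaks$lg, peaks$left_bin, peaks$right_bin)
  out <- peaks
  for (k in unique(key)) {
    rows <- peaks[key == k, ]
    if (length(unique(rows$season)) < 2) next
    comb <- rows[1, ]
    comb$season <- "combined"
    comb$add <- mean(rows$add)
    comb$dom <- mean(rows$dom)
    comb$pve <- mean(rows$pve)
    comb$lod <- NA_real_
    out <- rbind(out, comb)
  }
  rownames(out) <- NULL
  out
}

#' Naive per-marker association scan
#'
#' Plain linear-model F test of the phenotype on additive plus dominance
#' marker coding at every marker, used to cross-check the physical location
#' of interval-mapping peaks (no kinship or structure correction).
#'
#' @param mm a `marker_matrix`.
#' @param phenotypes data frame `line_id`, `value`.
#' @return data frame `chrom`, `pos`, `p`, `neglog10p`.
#' @export
association_scan <- function(mm, phenotypes) {
  ph <- phenotypes[!is.na(phenotypes$value), ]
  lines <- intersect(colnames(mm$geno), ph$line_id)
  if (length(lines) < 30) stop("need at least 30 phenotyped individuals")
  y_all <- ph$value[match(lines, ph$line_id)]
  g_all <- mm$geno[, lines, drop = FALSE]
  p <- vapply(seq_len(nrow(g_all)), function(i) {
    g <- g_all[i, ]
    ok <- !is.na(g)
    y <- y_all[ok]; g <- g[ok]
    n <- length(y)
    if (n < 10) return(NA_real_)
    X <- cbind(1, g - 1, as.numeric(g == 1))
    fit <- stats::lm.fit(X, y)
    q <- fit$rank - 1L
    if (q < 1) return(NA_real_)
    rss1 <- sum(fit$residuals^2)
    rss0 <- sum((y - mean(y))^2)
    if (rss1 <= 0) return(0)
    f <- ((rss0 - rss1) / q) / (rss1 / (n - fit$rank))
    stats::pf(f, q, n - fit$rank, lower.tail = FALSE)
  }, numeric(1))
  data.frame(chrom = mm$chrom, pos = mm$pos, p = p, neglog10p = -log10(p))
}

#' Filter candidate variants inside a QTL interval
#'
#' A variant passes when (1) both parents are homozygous with read depth
#' at least `min_depth`; (2) the change is protein-altering, judged by
#' translating the annotated reference codon and its parent-B substituted
#' counterpart with the standard genetic code (a site without usable
#' coding annotation is flagged indeterminate and never passed); and
#' (3) parent A matches the reference allele, or parent B differs from it.
#'
#' @param parent_variants data frame `chrom`, `pos`, `ref`, `alt`,
#'   `gt_a`, `gt_b` (allele-index genotypes such as `"0/0"`, `"1/1"`),
#'   `depth_a`, `depth_b`.
#' @param annotations data frame `chrom`, `pos`, `gene_id`, `codon_ref`
#'   (reference codon containing the site), `codon_pos` (1-3, position of
#'   the site inside the codon), optional `aa_pos`.
#' @param interval list or vector `chrom`, `start`, `end` (bp) delimiting
#'   the QTL interval.
#' @param min_depth parental depth threshold.
#' @return data frame with per-criterion logicals, `codon_change`,
#'   `aa_change`, `indeterminate` and overall `pass`.
#' @export
candidate_variant_filter <- function(parent_variants, annotations, interval,
                                     min_depth = 6) {
  v <- parent_variants
  inside <- v$chrom == interval$chrom & v$pos >= interval$start &
    v$pos <= interval$end
  v <- v[inside, , drop = FALSE]
  if (!nrow(v))
    return(cbind(v, crit_depth = logical(0), crit_protein = logical(0),
                 crit_reference = logical(0), indeterminate = logical(0),
                 codon_change = character(0), aa_change = character(0),
                 pass = logical(0)))
  allele_of <- function(gt, ref, alt) {
    a1 <- sub("[/|].*", "", gt); a2 <- sub(".*[/|]", "", gt)
    ifelse(a1 != a2 | a1 == ".", NA,
           ifelse(a1 == "0", ref, alt))
  }
  al_a <- allele_of(v$gt_a, v$ref, v$alt)
  al_b <- allele_of(v$gt_b, v$ref, v$alt)
  crit_depth <- !is.na(al_a) & !is.na(al_b) &
    v$depth_a >= min_depth & v$depth_b >= min_depth
  key <- paste(v$chrom, v$pos)
  ann <- annotations[match(key, paste(annotations$chrom, annotations$pos)), ]
  codon_change <- rep(NA_character_, nrow(v))
  aa_change <- rep(NA_character_, nrow(v))
  crit_protein <- rep(NA, nrow(v))
  snp <- nchar(v$ref) == 1 & nchar(v$alt) == 1
  for (i in seq_len(nrow(v))) {
    if (is.na(ann$codon_ref[i]) || !snp[i]) next
    cr <- toupper(ann$codon_ref[i])
    cp <- ann$codon_pos[i]
    if (is.na(cp) || nchar(cr) != 3 || cp < 1 || cp > 3) next
    if (substr(cr, cp, cp) != toupper(v$ref[i])) next  # inconsistent context
    ca <- cr
    substr(ca, cp, cp) <- toupper(v$alt[i])
    aa_r <- seqinr::translate(strsplit(cr, "")[[1]])
    aa_a <- seqinr::translate(strsplit(ca, "")[[1]])
    codon_change[i] <- paste0(cr, ">", ca)
    pos_tag <- if (!is.null(ann$aa_pos) && !is.na(ann$aa_pos[i]))
      ann$aa_pos[i] else ""
    aa_change[i] <- paste0(aa_r, pos_tag, aa_a)
    crit_protein[i] <- aa_r != aa_a
  }
  indeterminate <- is.na(crit_protein)
  crit_reference <- (al_a == v$ref) | (al_b != v$ref)
  crit_reference[is.na(crit_reference)] <- FALSE
  pass <- crit_depth & !indeterminate & crit_protein & crit_reference
  pass[is.na(pass)] <- FALSE
  cbind(v, crit_depth = crit_depth,
        crit_protein = ifelse(indeterminate, FALSE, crit_protein),
        crit_reference = crit_reference, indeterminate = indeterminate,
        codon_change = codon_change, aa_change = aa_change, pass = pass)
}
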