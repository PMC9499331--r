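#' Recombination fraction between two F2 markers (EM algorithm)
#'
#' Maximum-likelihood estimate of the recombination fraction r between two
#' codominant markers in an F2 intercross. The nine two-locus genotype
#' classes have multinomial probabilities determined by r; the
#' double-heterozygote class mixes the two phase configurations
#' (coupling/repulsion), so its expected number of recombinant gametes,
#' 2 r^2 / ((1-r)^2 + r^2), is imputed iteratively (EM). The LOD score is
#' log10 L(r-hat) / L(0.5).
#'
#' @param g1,g2 integer genotype codes 0/1/2/NA across the same
#'   individuals.
#' @param tol EM convergence tolerance on r.
#' @param max_iter maximum EM iterations.
#' @return list `r`, `lod`, `n` (individuals informative for both markers).
#' @export
estimate_rf <- function(g1, g2, tol = 1e-12, max_iter = 500) {
  ok <- !is.na(g1) & !is.na(g2)
  n <- sum(ok)
  if (n < 2) stop("need at least 2 individuals with both genotypes observed")
  N <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2)
    N[i + 1, j + 1] <- sum(g1[ok] == i & g2[ok] == j)
  ## recombinant gametes carried by each fully-informative class
  rec_fixed <- 1 * (N[1, 2] + N[2, 1] + N[2, 3] + N[3, 2]) +
               2 * (N[1, 3] + N[3, 1])
  n11 <- N[2, 2]
  r <- 0.25
  for (it in seq_len(max_iter)) {
    w <- 2 * r^2 / ((1 - r)^2 + r^2)   # E[rec gametes | double het]
    r_new <- (rec_fixed + n11 * w) / (2 * n)
    if (abs(r_new - r) < tol) { r <- r_new; break }
    r <- r_new
  }
  r <- min(max(r, 0), 0.5)
  ll <- function(r) {
    r <- min(max(r, 1e-12), 0.5)
    p <- matrix(c((1 - r)^2 / 4, r * (1 - r) / 2, r^2 / 4,
                  r * (1 - r) / 2, ((1 - r)^2 + r^2) / 2, r * (1 - r) / 2,
                  r^2 / 4, r * (1 - r) / 2, (1 - r)^2 / 4), 3, 3)
    sum(N[N > 0] * log(p[N > 0]))
  }
  lod <- (ll(r) - ll(0.5)) / log(10)
  list(r = r, lod = max(lod, 0), n = n)
}

#' Multinomial log-likelihood grid search for the F2 recombination fraction
#'
#' Independent brute-force maximizer of the same nine-class likelihood used
#' by [estimate_rf()], intended as a cross-check.
#'
#' @param g1,g2 genotype codes 0/1/2/NA.
#' @param step grid resolution on r.
#' @return The grid value of r maximizing the likelihood.
#' @export
rf_grid_search <- function(g1, g2, step = 1e-4) {
  ok <- !is.na(g1) & !is.na(g2)
  a <- g1[ok]; b <- g2[ok]
  N <- vapply(0:2, function(i) vapply(0:2, function(j)
    sum(a == i & b == j), numeric(1)), numeric(3))
  grid <- seq(step, 0.5, by = step)
  ll <- vapply(grid, function(r) {
    p <- matrix(c((1 - r)^2 / 4, r * (1 - r) / 2, r^2 / 4,
                  r * (1 - r) / 2, ((1 - r)^2 + r^2) / 2, r * (1 - r) / 2,
                  r^2 / 4, r * (1 - r) / 2, (1 - r)^2 / 4), 3, 3)
    sum(N[N > 0] * log(p[N > 0]))
  }, numeric(1))
  grid[which.max(ll)]
}

#' Mapping functions: recombination fraction to map distance
#'
#' Kosambi (default; allows partial crossover interference):
#' d = 25 ln((1+2r)/(1-2r)). Haldane (no interference):
#' d = -50 ln(1-2r). `map_rf()` is the exact inverse.
#'
#' @param r recombination fraction(s), `0 <= r < 0.5`.
#' @param fun `"kosambi"` or `"haldane"`.
#' @return Map distance in cM.
#' @export
map_distance <- function(r, fun = c("kosambi", "haldane")) {
  fun <- match.arg(fun)
  if (any(r < 0 | r >= 0.5)) stop("r must lie in [0, 0.5)")
  switch(fun,
         kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r)),
         haldane = -50 * log(1 - 2 * r))
}

#' @rdname map_distance
#' @param d map distance(s) in cM.
#' @export
map_rf <- function(d, fun = c("kosambi", "haldane")) {
  fun <- match.arg(fun)
  if (any(d < 0)) stop("distance must be >= 0")
  switch(fun,
         kosambi = tanh(d / 50) / 2,
         haldane = (1 - exp(-d / 50)) / 2)
}

## adjacent-pair r and LOD along an ordered set of bin genotype rows
.chain_rf <- function(geno) {
  n <- nrow(geno)
  if (n < 2) return(data.frame(r = numeric(0), lod = numeric(0)))
  out <- lapply(seq_len(n - 1), function(i)
    estimate_rf(geno[i, ], geno[i + 1, ]))
  data.frame(r = vapply(out, `[[`, numeric(1), "r"),
             lod = vapply(out, `[[`, numeric(1), "lod"))
}

## distances with r capped away from 0.5 so unlinked pairs give a large
## finite distance that trips the split rule
.chain_dist <- function(r, fun) map_distance(pmin(r, 0.4999), fun)

#' Build a genetic map with bins fixed in reference-genome order
#'
#' Bins on each chromosome are taken in physical order and adjacent
#' recombination fractions chained into cumulative cM positions. Two
#' departures from a clean chain are handled:
#'
#' * Discordant bins -- an interior bin (or block of up to `max_block`
#'   consecutive bins delimited by two adjacent distances above `jump_cm`)
#'   whose insertion at its physical rank inflates the local map length by
#'   more than `discord_cm` (d(prev, block) + d(block, next) -
#'   d(prev, next)) is removed from the chain and queued for rippling
#'   placement; the worst offender is peeled iteratively. The block rule
#'   catches mis-assembled segments, whose bins are tightly linked to each
#'   other but not to their physical neighbours.
#' * Splits -- the chain is cut into separate linkage groups wherever the
#'   adjacent distance exceeds `split_cm` or the linkage LOD falls below
#'   `split_lod`.
#'
#' @param bs a `bin_set` (only `kept` bins are used).
#' @param map_fun mapping function, `"kosambi"` or `"haldane"`.
#' @param split_cm,split_lod linkage-group split rules.
#' @param discord_cm local map-length inflation (cM) that marks a bin or
#'   block discordant.
#' @param jump_cm adjacent distance treated as a suspicious junction when
#'   searching for discordant blocks.
#' @param max_block largest discordant block considered (bins).
#' @return An object of class `genetic_map`: `table` (one row per mapped
#'   bin: `lg`, `bin_id`, `chrom`, `phys_start`, `phys_end`, `cm`,
#'   `redundant`, `relocated`), `map_fun`, `discordant` (bin ids awaiting
#'   placement), `unplaced`, `logs`.
#' @export
build_fixed_order_map <- function(bs, map_fun = c("kosambi", "haldane"),
                                  split_cm = 50, split_lod = 3,
                                  discord_cm = 10, jump_cm = 15,
                                  max_block = 10) {
  map_fun <- match.arg(map_fun)
  if (!all(bs$bins$kept)) bs <- filter_bins(bs)
  rows <- list(); discordant <- character(0)
  for (nm in unique(bs$bins$chrom)) {
    sel <- bs$bins$chrom == nm
    binfo <- bs$bins[sel, ]
    o <- order(binfo$start)
    binfo <- binfo[o, ]
    geno <- bs$geno[binfo$bin_id, , drop = FALSE]
    ## peel discordant interior bins and blocks
    repeat {
      n <- nrow(geno)
      if (n < 3) break
      chain <- .chain_rf(geno)
      d <- .chain_dist(chain$r, map_fun)
      best_infl <- -Inf; best_rng <- NULL
      ## single interior bins
      for (i in 2:(n - 1)) {
        skip <- estimate_rf(geno[i - 1, ], geno[i + 1, ])
        infl <- d[i - 1] + d[i] - .chain_dist(skip$r, map_fun)
        if (infl > best_infl) { best_infl <- infl; best_rng <- c(i, i) }
      }
      ## blocks delimited by two suspicious junctions
      jct <- which(d > jump_cm)
      if (length(jct) > 1) {
        for (a in jct) for (b in jct[jct > a & jct - a <= max_block]) {
          if (b + 1 > n) next
          skip <- estimate_rf(geno[a, ], geno[b + 1, ])
          infl <- d[a] + d[b] - .chain_dist(skip$r, map_fun)
          if (infl > best_infl) { best_infl <- infl; best_rng <- c(a + 1, b) }
        }
      }
      if (best_infl <= discord_cm) break
      rng <- best_rng[1]:best_rng[2]
      discordant <- c(discordant, binfo$bin_id[rng])
      binfo <- binfo[-rng, , drop = FALSE]
      geno <- geno[-rng, , drop = FALSE]
    }
    ## split into linkage groups
    n <- nrow(geno)
    chain <- .chain_rf(geno)
    d <- if (n > 1) .chain_dist(chain$r, map_fun) else numeric(0)
    cut <- if (n > 1) which(d > split_cm | chain$lod < split_lod) else integer(0)
    grp <- cumsum(c(1L, as.integer(seq_len(max(n - 1, 0)) %in% cut)))
    n_grp <- max(grp)
    for (g in seq_len(n_grp)) {
      idx <- which(grp == g)
      lg <- if (n_grp == 1) nm else paste0(nm, letters[g])
      dg <- if (length(idx) > 1) d[idx[-length(idx)]] else numeric(0)
      cm <- cumsum(c(0, dg))
      rows[[length(rows) + 1L]] <- data.frame(
        lg = lg, bin_id = binfo$bin_id[idx], chrom = nm,
        phys_start = binfo$start[idx], phys_end = binfo$end[idx],
        cm = cm, redundant = c(FALSE, dg < 1e-9), relocated = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, map_fun = map_fun,
                 discordant = discordant, unplaced = character(0),
                 logs = list()),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  lgs <- split(x$table, x$table$lg)
  cat("genetic_map:", nrow(x$table), "bins in", length(lgs),
      "linkage group(s),",
      round(sum(vapply(lgs, function(g) max(g$cm), numeric(1))), 1),
      "cM total\n")
  if (length(x$discordant)) cat(" ", length(x$discordant),
                                "discordant bins pending placement\n")
  if (length(x$unplaced)) cat(" ", length(x$unplaced), "bins unplaced\n")
  invisible(x)
}

## recompute cumulative cM (and redundancy flags) of one LG from its chain
.recompute_lg <- function(tab, geno, lg, map_fun) {
  idx <- which(tab$lg == lg)
  if (length(idx) < 2) {
    tab$cm[idx] <- 0; tab$redundant[idx] <- FALSE
    return(tab)
  }
  chain <- .chain_rf(geno[tab$bin_id[idx], , drop = FALSE])
  d <- .chain_dist(chain$r, map_fun)
  tab$cm[idx] <- cumsum(c(0, d))
  tab$redundant[idx] <- c(FALSE, d < 1e-9)
  tab
}

#' Place a discordant bin by rippling
#'
#' The inquiry bin is compared against every mapped bin; the most tightly
#' linked one (smallest r) with linkage LOD at least `lod_min` becomes the
#' target, and the inquiry is inserted on the side of the target that adds
#' the least map length. Without a qualifying target the bin is left
#' unplaced and logged.
#'
#' @param map a `genetic_map`.
#' @param bs the `bin_set` carrying genotypes for mapped and inquiry bins.
#' @param bin_id inquiry bin id.
#' @param lod_min minimum linkage LOD for accepting a target.
#' @return The updated `genetic_map`.
#' @export
ripple_place_discordant <- function(map, bs, bin_id, lod_min = 6) {
  tab <- map$table
  gq <- bs$geno[bin_id, ]
  cand <- lapply(tab$bin_id, function(b) estimate_rf(bs$geno[b, ], gq))
  r <- vapply(cand, `[[`, numeric(1), "r")
  lod <- vapply(cand, `[[`, numeric(1), "lod")
  ok <- lod >= lod_min
  map$discordant <- setdiff(map$discordant, bin_id)
  if (!any(ok)) {
    map$unplaced <- union(map$unplaced, bin_id)
    return(map)
  }
  tgt <- which(ok)[which.min(r[ok])]
  lg <- tab$lg[tgt]
  idx <- which(tab$lg == lg)
  pos_in_lg <- match(tgt, idx)
  dist_to <- function(i, j) {  # added length when inserting between i and j
    di <- if (is.na(i)) 0 else
      .chain_dist(estimate_rf(bs$geno[tab$bin_id[i], ], gq)$r, map$map_fun)
    dj <- if (is.na(j)) 0 else
      .chain_dist(estimate_rf(bs$geno[tab$bin_id[j], ], gq)$r, map$map_fun)
    dij <- if (is.na(i) || is.na(j)) 0 else
      .chain_dist(estimate_rf(tab_geno(bs, tab, i), tab_geno(bs, tab, j))$r,
                  map$map_fun)
    di + dj - dij
  }
  left_nb <- if (pos_in_lg > 1) idx[pos_in_lg - 1] else NA
  right_nb <- if (pos_in_lg < length(idx)) idx[pos_in_lg + 1] else NA
  add_left <- dist_to(left_nb, tgt)
  add_right <- dist_to(tgt, right_nb)
  after <- if (add_left <= add_right) tgt - 1L else tgt
  new_row <- data.frame(
    lg = lg, bin_id = bin_id,
    chrom = bs$bins$chrom[match(bin_id, bs$bins$bin_id)],
    phys_start = bs$bins$start[match(bin_id, bs$bins$bin_id)],
    phys_end = bs$bins$end[match(bin_id, bs$bins$bin_id)],
    cm = NA_real_, redundant = FALSE, relocated = FALSE)
  tab <- rbind(tab[seq_len(after), , drop = FALSE], new_row,
               tab[setdiff(seq_len(nrow(tab)), seq_len(after)), , drop = FALSE])
  rownames(tab) <- NULL
  lg_chrom <- tab$chrom[tab$lg == lg & tab$bin_id != bin_id][1]
  tab$relocated[tab$bin_id == bin_id] <- !identical(
    tab$chrom[tab$bin_id == bin_id], lg_chrom)
  map$table <- .recompute_lg(tab, bs$geno, lg, map$map_fun)
  map$logs$placed <- c(map$logs$placed, stats::setNames(lg, bin_id))
  map
}

tab_geno <- function(bs, tab, i) bs$geno[tab$bin_id[i], ]

#' Correct bin genotype errors and merge redundant bins, to a fixpoint
#'
#' Repeats three steps until nothing changes: (1) a genotype implying a
#' double recombination around a single bin within `dd_max` cM -- both
#' flanking bins agree and the middle one differs -- is replaced by the
#' flanking genotype, and missing bin genotypes are imputed from agreeing
#' flanks; (2) physically consecutive bins at the same genetic position are
#' merged (extent = union, genotypes = consensus, first id kept); (3) the
#' linkage chain is re-estimated.
#'
#' @param map a `genetic_map`.
#' @param bs the matching `bin_set`.
#' @param dd_max flanking window (cM) within which a lone double
#'   recombinant is treated as a genotyping error.
#' @param max_iter safety cap on correction/merge passes.
#' @return list `map`, `bins` (updated `bin_set`), `n_corrections`,
#'   `n_merged`, `iterations`.
#' @export
correct_and_merge <- function(map, bs, dd_max = 5, max_iter = 25) {
  tab <- map$table
  geno <- bs$geno
  bins <- bs$bins
  total_corr <- 0L; total_merge <- 0L; iter <- 0L
  repeat {
    iter <- iter + 1L
    changed <- FALSE
    ## --- step 1: corrections ------------------------------------------
    for (lg in unique(tab$lg)) {
      idx <- which(tab$lg == lg)
      if (length(idx) < 3) next
      ids <- tab$bin_id[idx]
      cm <- tab$cm[idx]
      for (i in 2:(length(idx) - 1)) {
        gl <- geno[ids[i - 1], ]; gm <- geno[ids[i], ]; gr <- geno[ids[i + 1], ]
        agree <- !is.na(gl) & !is.na(gr) & gl == gr
        near <- (cm[i + 1] - cm[i - 1]) < dd_max
        fix <- agree & ((near & !is.na(gm) & gm != gl) | is.na(gm))
        if (any(fix)) {
          geno[ids[i], fix] <- gl[fix]
          total_corr <- total_corr + sum(fix & !is.na(gm))
          changed <- TRUE
        }
      }
    }
    ## --- step 2: merges ------------------------------------------------
    for (lg in unique(tab$lg)) {
      repeat {
        idx <- which(tab$lg == lg)
        if (length(idx) < 2) break
        i <- NULL
        for (j in seq_len(length(idx) - 1)) {
          a <- idx[j]; b <- idx[j + 1]
          same_cm <- abs(tab$cm[b] - tab$cm[a]) < 1e-9
          consec <- tab$chrom[a] == tab$chrom[b] &&
            abs(tab$phys_end[a] - tab$phys_start[b]) < 1e-9
          if (same_cm && consec) { i <- j; break }
        }
        if (is.null(i)) break
        a <- idx[i]; b <- idx[i + 1]
        ida <- tab$bin_id[a]; idb <- tab$bin_id[b]
        ga <- geno[ida, ]; gb <- geno[idb, ]
        ga[is.na(ga)] <- gb[is.na(ga)]
        geno[ida, ] <- ga
        tab$phys_end[a] <- tab$phys_end[b]
        ka <- match(ida, bins$bin_id); kb <- match(idb, bins$bin_id)
        bins$end[ka] <- bins$end[kb]
        bins$anchor_last[ka] <- bins$anchor_last[kb]
        bins$n_anchors[ka] <- bins$n_anchors[ka] + bins$n_anchors[kb]
        bins <- bins[-kb, , drop = FALSE]
        geno <- geno[rownames(geno) != idb, , drop = FALSE]
        tab <- tab[-b, , drop = FALSE]
        total_merge <- total_merge + 1L
        changed <- TRUE
        map$logs$merged <- c(map$logs$merged, stats::setNames(ida, idb))
      }
    }
    ## --- step 3: re-estimate linkage -----------------------------------
    for (lg in unique(tab$lg)) tab <- .recompute_lg(tab, geno, lg, map$map_fun)
    if (!changed || iter >= max_iter) break
  }
  rownames(tab) <- NULL
  map$table <- tab
  bs$geno <- geno
  bs$bins <- bins
  list(map = map, bins = bs, n_corrections = total_corr,
       n_merged = total_merge, iterations = iter)
}

#' Full bin-map construction pipeline
#'
#' Chains [build_fixed_order_map()], rippling placement of every discordant
#' bin, and [correct_and_merge()].
#'
#' @inheritParams build_fixed_order_map
#' @param lod_min rippling acceptance LOD.
#' @param dd_max error-correction window (cM).
#' @return list `map` (a `genetic_map`), `bins` (the corrected/merged
#'   `bin_set`), `n_corrections`, `n_merged`.
#' @export
build_map <- function(bs, map_fun = c("kosambi", "haldane"), split_cm = 50,
                      split_lod = 3, discord_cm = 10, lod_min = 6,
                      dd_max = 5) {
  map_fun <- match.arg(map_fun)
  if (!all(bs$bins$kept)) bs <- filter_bins(bs)
  map <- build_fixed_order_map(bs, map_fun, split_cm, split_lod, discord_cm)
  for (b in map$discordant) map <- ripple_place_discordant(map, bs, b)
  res <- correct_and_merge(map, bs, dd_max = dd_max)
  list(map = res$map, bins = res$bins,
       n_corrections = res$n_corrections, n_merged = res$n_merged)
}

#' Summary statistics of a genetic map
#'
#' Per linkage group and in total: genetic length, bin and effective-bin
#' counts (effective = total - redundant, a redundant bin sharing its cM
#' position with its predecessor), nominal and effective mean adjacent
#' spacing (total length over total adjacent gaps), physical span from the
#' first bin's start to the last bin's end (relocated bins excluded), and
#' coverage = span / full chromosome length x 100 (rounded to 2 decimals).
#'
#' @param map a `genetic_map`.
#' @param chrom_lengths named vector of full chromosome lengths (bp).
#' @return data frame with one row per linkage group plus a `Total` row.
#' @export
map_summary <- function(map, chrom_lengths) {
  tab <- map$table
  lgs <- unique(tab$lg)
  per <- lapply(lgs, function(lg) {
    g <- tab[tab$lg == lg, ]
    n <- nrow(g)
    n_eff <- n - sum(g$redundant)
    len <- max(g$cm)
    own <- g[!g$relocated, ]
    span <- if (nrow(own)) (max(own$phys_end) - min(own$phys_start)) / 1e6 else NA
    chrom <- g$chrom[!g$relocated][1]
    data.frame(lg = lg, chrom = chrom, length_cm = len, n_bins = n,
               n_effective = n_eff,
               spacing_nominal = if (n > 1) len / (n - 1) else NA,
               spacing_effective = if (n_eff > 1) len / (n_eff - 1) else NA,
               span_mb = span)
  })
  out <- do.call(rbind, per)
  ## full length and coverage per LG: whole chromosome when it maps to a
  ## single LG; otherwise the chromosome total is apportioned to the
  ## chromosome-level row only
  out$full_mb <- chrom_lengths[out$chrom] / 1e6
  multi <- names(which(table(out$chrom) > 1))
  out$coverage_pct <- ifelse(out$chrom %in% multi, NA,
                             round(out$span_mb / out$full_mb * 100, 2))
  ## chromosome-union span for totals (split chromosomes counted once)
  span_by_chrom <- vapply(unique(out$chrom), function(ch) {
    g <- tab[tab$chrom == ch & !tab$relocated, ]
    (max(g$phys_end) - min(g$phys_start)) / 1e6
  }, numeric(1))
  tot_span <- sum(span_by_chrom)
  tot_full <- sum(chrom_lengths[unique(out$chrom)]) / 1e6
  total <- data.frame(
    lg = "Total", chrom = NA, length_cm = sum(out$length_cm),
    n_bins = sum(out$n_bins), n_effective = sum(out$n_effective),
    spacing_nominal = sum(out$length_cm) / sum(pmax(out$n_bins - 1, 0)),
    spacing_effective = sum(out$length_cm) / sum(pmax(out$n_effective - 1, 0)),
    span_mb = tot_span, full_mb = tot_full,
    coverage_pct = round(tot_span / tot_full * 100, 2))
  rbind(out, total)
}

## continuous piecewise-linear least squares: y ~ x with hinge terms at the
## given breakpoints; returns per-segment slopes and RSS
.fit_piecewise <- function(x, y, breaks) {
  X <- cbind(1, x)
  for (b in breaks) X <- cbind(X, pmax(x - b, 0))
  fit <- stats::lm.fit(X, y)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  list(slopes = cumsum(co[-1]), rss = sum(fit$residuals^2))
}

#' Region-wise ratio of genetic to physical distance (RGP profile)
#'
#' Fits a continuous piecewise-linear curve of genetic position (cM)
#' against physical position (Mb) for each chromosome by least squares,
#' searching breakpoints over the bin grid. A three-segment fit captures
#' the common high--low--high pattern (distal regions I and III
#' recombining freely, pericentromeric region II suppressed); a
#' two-segment fit is retained when it is not materially worse (BIC),
#' covering chromosomes lacking a terminal region. Slopes are the
#' region-wise RGP in cM/Mb.
#'
#' Chromosomes split across several linkage groups are concatenated in
#' physical order with their cM scales made cumulative.
#'
#' @param map a `genetic_map`.
#' @param min_bins minimum mapped bins per chromosome to attempt a fit.
#' @param n_candidates breakpoint candidates per chromosome.
#' @return data frame `chrom`, `region`, `start_mb`, `end_mb`, `rgp`.
#' @export
rgp_profile <- function(map, min_bins = 6, n_candidates = 25) {
  tab <- map$table[!map$table$relocated, ]
  out <- list()
  for (nm in unique(tab$chrom)) {
    g <- tab[tab$chrom == nm, ]
    if (nrow(g) < min_bins) next
    g <- g[order(g$phys_start), ]
    ## make cm cumulative across LGs in physical order
    y <- g$cm
    if (length(unique(g$lg)) > 1) {
      off <- 0
      for (lg in unique(g$lg)) {
        sel <- g$lg == lg
        y[sel] <- g$cm[sel] - min(g$cm[sel]) + off
        off <- max(y[sel])
      }
    }
    x <- (g$phys_start + g$phys_end) / 2 / 1e6
    cand <- unique(stats::quantile(x, probs = seq(0.1, 0.9,
                                                  length.out = n_candidates),
                                   names = FALSE))
    n <- length(x)
    best2 <- NULL; best3 <- NULL
    for (b1 in cand) {
      f <- .fit_piecewise(x, y, b1)
      if (is.null(best2) || f$rss < best2$rss)
        best2 <- c(f, list(breaks = b1))
    }
    pairs <- utils::combn(cand, 2)
    for (k in seq_len(ncol(pairs))) {
      f <- .fit_piecewise(x, y, pairs[, k])
      if (is.null(best3) || f$rss < best3$rss)
        best3 <- c(f, list(breaks = pairs[, k]))
    }
    bic <- function(f, p) n * log(max(f$rss, 1e-12) / n) + p * log(n)
    use3 <- bic(best3, 6) < bic(best2, 4)
    best <- if (use3) best3 else best2
    bnd <- c(min(x), best$breaks, max(x))
    regions <- if (use3) c("I", "II", "III") else c("II", "III")
    out[[nm]] <- data.frame(chrom = nm, region = regions,
                            start_mb = bnd[-length(bnd)], end_mb = bnd[-1],
                            rgp = as.numeric(best$slopes))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a genetic map and its summary as TSV files
#'
#' @param map a `genetic_map`.
#' @param dir output directory.
#' @param chrom_lengths optional; when given, `map_summary.tsv` is written
#'   too.
#' @return Invisibly, the paths written.
#' @export
write_genetic_map <- function(map, dir, chrom_lengths = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, "genetic_map.tsv")
  utils::write.table(map$table, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- p
  if (!is.null(chrom_lengths)) {
    p2 <- file.path(dir, "map_summary.tsv")
    utils::write.table(map_summary(map, chrom_lengths), p2, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p2)
  }
  invisible(paths)
}
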