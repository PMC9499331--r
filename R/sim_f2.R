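#' Specify a synthetic genome for F2 simulation
#'
#' A map specification couples physical chromosome lengths with genetic
#' lengths and two piecewise-constant profiles: a recombination profile
#' (relative cM/Mb weights, emulating the high--low--high pattern of distal
#' recombination and pericentromeric suppression) and a marker-density
#' profile (relative markers/Mb, emulating dense distal and sparse
#' pericentromeric marker coverage).
#'
#' Profiles are given as relative weights over physical intervals that tile
#' each chromosome; they are rescaled internally so that the integral of the
#' recombination profile equals the chromosome's genetic length.
#'
#' @param chromosomes data frame with columns `name`, `length_bp`,
#'   `length_cm`.
#' @param recombination_profile named list (by chromosome) of data frames
#'   with columns `start`, `end`, `weight` (relative cM/Mb); `NULL` for a
#'   uniform profile.
#' @param marker_density_profile same layout, relative markers/Mb; `NULL`
#'   for uniform density.
#' @return An object of class `map_spec`.
#' @seealso [default_map_spec()] for the stock three-chromosome genome.
#' @export
map_spec <- function(chromosomes, recombination_profile = NULL,
                     marker_density_profile = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length_bp", "length_cm") %in% names(chromosomes)))
  if (any(chromosomes$length_bp <= 0)) stop("physical lengths must be positive")
  if (any(chromosomes$length_cm < 0)) stop("genetic lengths must be >= 0")
  chromosomes$name <- as.character(chromosomes$name)
  check_profile <- function(prof, what) {
    if (is.null(prof)) return(invisible(NULL))
    for (nm in chromosomes$name) {
      p <- prof[[nm]]
      if (is.null(p)) stop("missing ", what, " profile for chromosome ", nm)
      L <- chromosomes$length_bp[chromosomes$name == nm]
      if (any(p$weight < 0)) stop(what, " weights must be >= 0")
      o <- order(p$start)
      p <- p[o, ]
      if (p$start[1] != 0 || p$end[nrow(p)] != L ||
          (nrow(p) > 1 && any(p$start[-1] != p$end[-nrow(p)])))
        stop(what, " profile must tile chromosome ", nm, " exactly")
    }
  }
  check_profile(recombination_profile, "recombination")
  check_profile(marker_density_profile, "marker density")
  structure(list(chromosomes = chromosomes,
                 recombination_profile = recombination_profile,
                 marker_density_profile = marker_density_profile),
            class = "map_spec")
}

#' Stock synthetic genome: 3 chromosomes, 80 Mb / 150 cM each
#'
#' Each chromosome carries a three-region structure: distal regions with
#' high recombination (and high marker density) flanking a broad
#' low-recombination middle region, the pattern seen when a genetic map is
#' compared with its physical map.
#'
#' @param n_chrom number of chromosomes.
#' @param length_bp physical length per chromosome (bp).
#' @param length_cm genetic length per chromosome (cM).
#' @param region_fracs fractions of physical length in regions I/II/III.
#' @param rgp_weights relative cM/Mb weights of the three regions.
#' @param density_weights relative markers/Mb weights of the three regions.
#' @return A `map_spec`.
#' @export
default_map_spec <- function(n_chrom = 3, length_bp = 8e7, length_cm = 150,
                             region_fracs = c(0.15, 0.70, 0.15),
                             rgp_weights = c(5, 0.3, 5),
                             density_weights = c(3, 1, 3)) {
  stopifnot(length(region_fracs) == 3, abs(sum(region_fracs) - 1) < 1e-9)
  nm <- sprintf("chr%02d", seq_len(n_chrom))
  chroms <- data.frame(name = nm, length_bp = length_bp, length_cm = length_cm)
  bounds <- c(0, cumsum(region_fracs)) * length_bp
  prof <- function(w) {
    p <- data.frame(start = bounds[1:3], end = bounds[2:4], weight = w)
    stats::setNames(rep(list(p), n_chrom), nm)
  }
  map_spec(chroms, recombination_profile = prof(rgp_weights),
           marker_density_profile = prof(density_weights))
}

## cumulative genetic position (cM) at physical breakpoints; weights rescaled
## so the chromosome's total equals length_cm
.gen_cum <- function(spec, chrom) {
  i <- match(chrom, spec$chromosomes$name)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  L <- spec$chromosomes$length_bp[i]
  G <- spec$chromosomes$length_cm[i]
  p <- spec$recombination_profile[[chrom]]
  if (is.null(p)) p <- data.frame(start = 0, end = L, weight = 1)
  p <- p[order(p$start), ]
  seg <- (p$end - p$start) * p$weight
  tot <- sum(seg)
  if (tot <= 0) {
    cum <- c(0, cumsum((p$end - p$start) * 0))
  } else {
    cum <- c(0, cumsum(seg)) * (G / tot)
  }
  list(breaks = c(p$start, L), cum = cum, L = L, G = G)
}

#' Convert physical position to genetic position
#'
#' Piecewise-linear interpolation of the cumulative recombination profile.
#'
#' @param spec a `map_spec`.
#' @param chrom chromosome name.
#' @param bp physical positions (bp).
#' @return Genetic positions in cM.
#' @export
phys_to_cm <- function(spec, chrom, bp) {
  g <- .gen_cum(spec, chrom)
  if (any(bp < 0 | bp > g$L)) stop("position outside chromosome ", chrom)
  stats::approx(g$breaks, g$cum, xout = bp, ties = "ordered")$y
}

#' @rdname phys_to_cm
#' @param cm genetic positions (cM).
#' @export
cm_to_phys <- function(spec, chrom, cm) {
  g <- .gen_cum(spec, chrom)
  if (any(cm < 0 | cm > g$G + 1e-9)) stop("genetic position outside chromosome ", chrom)
  # invert the (weakly) monotone cumulative curve; flat stretches map to
  # their left edge
  stats::approx(g$cum, g$breaks, xout = pmin(cm, g$G), ties = "ordered")$y
}

#' Sample marker positions along a synthetic genome
#'
#' Positions are drawn from the marker-density profile (uniform if absent),
#' de-duplicated and sorted. The realized count can fall slightly short of
#' `n_markers` after de-duplication.
#'
#' @param spec a `map_spec`.
#' @param n_markers total marker count across the genome.
#' @param seed integer seed.
#' @return data frame with columns `chrom`, `pos`.
#' @export
sample_marker_positions <- function(spec, n_markers, seed) {
  set.seed(seed)
  ch <- spec$chromosomes
  mass <- vapply(ch$name, function(nm) {
    p <- spec$marker_density_profile[[nm]]
    if (is.null(p)) return(ch$length_bp[ch$name == nm])
    sum((p$end - p$start) * p$weight)
  }, numeric(1))
  n_per <- round(n_markers * mass / sum(mass))
  out <- lapply(seq_len(nrow(ch)), function(i) {
    nm <- ch$name[i]
    n <- n_per[i]
    p <- spec$marker_density_profile[[nm]]
    if (is.null(p)) p <- data.frame(start = 0, end = ch$length_bp[i], weight = 1)
    p <- p[order(p$start), ]
    seg <- (p$end - p$start) * p$weight
    k <- as.vector(stats::rmultinom(1, n, seg / sum(seg)))
    pos <- unlist(lapply(seq_along(k), function(j)
      stats::runif(k[j], p$start[j], p$end[j])))
    pos <- sort(unique(as.integer(round(pos))))
    pos <- pos[pos >= 1 & pos <= ch$length_bp[i]]
    data.frame(chrom = nm, pos = pos)
  })
  do.call(rbind, out)
}

#' Sample meiotic crossovers for a set of gametes
#'
#' No-interference model: the crossover count per gamete is
#' Poisson(L/100) for a chromosome of genetic length L cM, with positions
#' uniform on (0, L).
#'
#' @param genetic_length_cm chromosome genetic length (cM).
#' @param n_gametes number of gametes to draw.
#' @param seed optional integer seed.
#' @return List of sorted numeric vectors of crossover positions (cM).
#' @export
sample_crossovers <- function(genetic_length_cm, n_gametes, seed = NULL) {
  if (genetic_length_cm < 0) stop("genetic length must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n_xo <- stats::rpois(n_gametes, genetic_length_cm / 100)
  lapply(n_xo, function(k) sort(stats::runif(k, 0, genetic_length_cm)))
}

## allele (0/1) carried by a gamete at genetic positions `cm`
.gamete_allele <- function(start_allele, crossovers, cm) {
  (start_allele + findInterval(cm, crossovers)) %% 2L
}

#' Simulate true F2 genotypes at given marker positions
#'
#' Each F2 individual is the union of two independent gametes per
#' chromosome; each gamete starts on a random parental strand and switches
#' strand at its crossovers. Genotypes are coded 0 (parent-A homozygote),
#' 1 (heterozygote), 2 (parent-B homozygote). The latent crossover record
#' is retained for oracle checks.
#'
#' An optional segregation-distortion knob resamples, with probability `s`,
#' whole individuals whose genotype at a given locus equals `against`,
#' emulating partial selection against one genotype class.
#'
#' @param spec a `map_spec`.
#' @param n_individuals F2 population size.
#' @param marker_positions data frame `chrom`, `pos` (bp), as from
#'   [sample_marker_positions()].
#' @param seed integer seed.
#' @param distortion optional list `(chrom, pos_cm, against, s)`.
#' @return An object of class `f2_sim` with elements `geno`
#'   (markers x individuals integer matrix), `chrom`, `pos`, `pos_cm`,
#'   `spec`, and the latent `meioses` record.
#' @export
simulate_f2_genotypes <- function(spec, n_individuals, marker_positions, seed,
                                  distortion = NULL) {
  set.seed(seed)
  mp <- marker_positions[order(match(marker_positions$chrom,
                                     spec$chromosomes$name),
                               marker_positions$pos), ]
  for (nm in unique(mp$chrom)) {
    L <- spec$chromosomes$length_bp[spec$chromosomes$name == nm]
    if (!length(L)) stop("marker on unknown chromosome ", nm)
    if (any(mp$pos[mp$chrom == nm] < 1 | mp$pos[mp$chrom == nm] > L))
      stop("marker outside chromosome ", nm)
  }
  ids <- sprintf("F%03d", seq_len(n_individuals))
  geno <- matrix(NA_integer_, nrow(mp), n_individuals,
                 dimnames = list(NULL, ids))
  pos_cm <- numeric(nrow(mp))
  meioses <- list()
  for (nm in spec$chromosomes$name) {
    idx <- which(mp$chrom == nm)
    if (!length(idx)) next
    G <- spec$chromosomes$length_cm[spec$chromosomes$name == nm]
    mcm <- phys_to_cm(spec, nm, mp$pos[idx])
    pos_cm[idx] <- mcm
    draw_ind <- function() {
      xo <- sample_crossovers(G, 2)
      st <- stats::rbinom(2, 1, 0.5)
      list(xo = xo, start = st)
    }
    dist_here <- !is.null(distortion) && identical(distortion$chrom, nm)
    inds <- vector("list", n_individuals)
    for (i in seq_len(n_individuals)) {
      repeat {
        ind <- draw_ind()
        if (!dist_here) break
        gq <- .gamete_allele(ind$start[1], ind$xo[[1]], distortion$pos_cm) +
              .gamete_allele(ind$start[2], ind$xo[[2]], distortion$pos_cm)
        if (gq != distortion$against || stats::runif(1) >= distortion$s) break
      }
      inds[[i]] <- ind
      geno[idx, i] <- .gamete_allele(ind$start[1], ind$xo[[1]], mcm) +
                      .gamete_allele(ind$start[2], ind$xo[[2]], mcm)
    }
    meioses[[nm]] <- inds
  }
  structure(list(geno = geno, chrom = mp$chrom, pos = mp$pos, pos_cm = pos_cm,
                 individuals = ids, spec = spec, meioses = meioses),
            class = "f2_sim")
}

#' True genotype of each individual at an arbitrary genetic position
#'
#' Evaluated from the latent crossover record, not from marker data.
#'
#' @param f2 an `f2_sim`.
#' @param chrom chromosome name.
#' @param cm genetic position (cM).
#' @return Integer vector of codes 0/1/2, one per individual.
#' @export
genotype_at <- function(f2, chrom, cm) {
  inds <- f2$meioses[[chrom]]
  if (is.null(inds)) stop("no meioses simulated for chromosome ", chrom)
  vapply(inds, function(ind)
    as.integer(.gamete_allele(ind$start[1], ind$xo[[1]], cm) +
               .gamete_allele(ind$start[2], ind$xo[[2]], cm)),
    integer(1))
}

#' Describe the per-marker sequencing depth model
#'
#' @param mode `"fixed"` (every marker of every individual sequenced at
#'   exactly `k` reads) or `"poisson"` (depth ~ Poisson(`k`)).
#' @param k depth (fixed mode) or mean depth (Poisson mode); `k >= 0`.
#' @param base_error per-read probability of reporting the wrong allele.
#' @return An object of class `depth_model`.
#' @export
depth_model <- function(mode = c("fixed", "poisson"), k = 2, base_error = 0) {
  mode <- match.arg(mode)
  stopifnot(k >= 0, base_error >= 0, base_error < 0.5)
  structure(list(mode = mode, k = k, base_error = base_error),
            class = "depth_model")
}

#' Apply a low-depth read-sampling model to true genotypes
#'
#' For each marker x individual cell, a depth is drawn from the model and
#' that many read alleles are sampled: a heterozygote yields each allele
#' with probability 1/2 per read, so it is called heterozygous only when
#' both alleles are seen, and miscalled homozygous with probability
#' 2 * (1/2)^k = 1/2^(k-1). Depth 0 yields a missing call. Homozygotes are
#' read correctly unless `base_error > 0`, in which case each read reports
#' the wrong allele with that probability.
#'
#' @param x an `f2_sim` or an integer matrix of codes 0/1/2.
#' @param model a [depth_model()].
#' @param seed integer seed.
#' @return A `marker_matrix` (when `x` is an `f2_sim`) or a plain matrix of
#'   observed codes 0/1/2/NA.
#' @export
apply_sequencing_model <- function(x, model, seed) {
  set.seed(seed)
  true <- if (inherits(x, "f2_sim")) x$geno else x
  stopifnot(is.matrix(true))
  n <- length(true)
  depth <- switch(model$mode,
                  fixed = rep.int(as.integer(model$k), n),
                  poisson = stats::rpois(n, model$k))
  obs <- matrix(NA_integer_, nrow(true), ncol(true),
                dimnames = dimnames(true))
  covered <- depth > 0 & !is.na(true)
  het <- covered & true == 1L
  if (any(het)) {
    nb <- stats::rbinom(sum(het), depth[het], 0.5)  # reads showing allele B
    obs[het] <- ifelse(nb == 0L, 0L, ifelse(nb == depth[het], 2L, 1L))
  }
  hom <- covered & true != 1L
  if (any(hom)) {
    if (model$base_error > 0) {
      nw <- stats::rbinom(sum(hom), depth[hom], model$base_error)  # wrong reads
      same <- true[hom]
      opp <- 2L - same
      obs[hom] <- ifelse(nw == 0L, same, ifelse(nw == depth[hom], opp, 1L))
    } else {
      obs[hom] <- true[hom]
    }
  }
  if (inherits(x, "f2_sim"))
    marker_matrix(obs, x$chrom, x$pos)
  else obs
}

#' Specify a simulated QTL
#'
#' Effects follow the usual F2 parameterization: genotype codes 0/1/2 give
#' additive scores x = -1/0/+1 and the dominance deviation applies to the
#' heterozygote. For F2:3 line means the heterozygote's dominance
#' contribution is halved (an F3 family from a het parent segregates 1:2:1,
#' so its mean carries d/2).
#'
#' @param chrom chromosome carrying the QTL.
#' @param pos_cm genetic position (cM).
#' @param a additive effect (trait units; positive means the parent-B
#'   allele increases the trait).
#' @param d dominance effect.
#' @param residual_sd environmental SD of F2:3 line means; must be > 0.
#' @param mu trait grand mean.
#' @param ordinal_max if non-`NULL`, line means are rounded and clipped to
#'   the ordinal scale 0..`ordinal_max`.
#' @return An object of class `qtl_spec`.
#' @export
qtl_spec <- function(chrom, pos_cm, a, d = 0, residual_sd = 1, mu = 0,
                     ordinal_max = NULL) {
  stopifnot(residual_sd > 0)
  structure(list(chrom = chrom, pos_cm = pos_cm, a = a, d = d,
                 residual_sd = residual_sd, mu = mu,
                 ordinal_max = ordinal_max),
            class = "qtl_spec")
}

#' Simulate F2:3 line-mean phenotypes from a single QTL
#'
#' Line mean = mu + x a + z d + e with x in \{-1, 0, +1\} from the F2
#' parent's QTL genotype, z = 1/2 for heterozygous parents and 0 otherwise,
#' and e ~ N(0, residual_sd^2).
#'
#' @param f2 an `f2_sim`.
#' @param qtl a [qtl_spec()]; its position must lie on a simulated
#'   chromosome.
#' @param lines individual ids to phenotype (default: all).
#' @param trait,season labels copied into the output.
#' @param seed integer seed.
#' @return data frame `line_id`, `trait`, `season`, `value`.
#' @export
simulate_f23_phenotypes <- function(f2, qtl, lines = NULL, trait = "trait",
                                    season = 1L, seed) {
  set.seed(seed)
  if (is.null(lines)) lines <- f2$individuals
  g <- genotype_at(f2, qtl$chrom, qtl$pos_cm)[match(lines, f2$individuals)]
  x <- g - 1L
  z <- ifelse(g == 1L, 0.5, 0)
  val <- qtl$mu + x * qtl$a + z * qtl$d +
    stats::rnorm(length(lines), 0, qtl$residual_sd)
  if (!is.null(qtl$ordinal_max))
    val <- pmin(pmax(round(val), 0), qtl$ordinal_max)
  data.frame(line_id = lines, trait = trait, season = season, value = val)
}

#' Introduce a mis-assembled segment into marker coordinates
#'
#' Emulates a reference-assembly error: the sequence physically labelled
#' `segment` on `source_chrom` truly belongs to `target_chrom`. Markers of
#' `target_chrom` lying in the `donor` interval are relabelled onto
#' `source_chrom` with coordinates mapped linearly into `segment` (their
#' genotype columns -- hence their genetic linkage -- are untouched), and
#' any original `source_chrom` markers inside `segment` are dropped. The
#' returned truth record keeps each relocated marker's genuine home.
#'
#' @param x an `f2_sim` or `marker_matrix`.
#' @param source_chrom chromosome that wrongly carries the segment.
#' @param segment numeric `c(start, end)` on `source_chrom` (bp).
#' @param target_chrom chromosome the sequence really belongs to.
#' @param donor numeric `c(start, end)` on `target_chrom`; defaults to the
#'   same coordinates as `segment`.
#' @return list with `data` (modified copy of `x`) and `truth` (data frame
#'   `assembled_chrom`, `assembled_pos`, `true_chrom`, `true_pos`).
#' @export
simulate_misassembly <- function(x, source_chrom, segment, target_chrom,
                                 donor = segment) {
  stopifnot(length(segment) == 2, length(donor) == 2,
            segment[2] >= segment[1], donor[2] >= donor[1])
  if (diff(segment) > 0 && abs(diff(donor) - diff(segment)) > 0)
    segment[2] <- segment[1] + diff(donor)
  sel_donor <- x$chrom == target_chrom & x$pos >= donor[1] & x$pos < donor[2]
  sel_drop <- x$chrom == source_chrom & x$pos >= segment[1] & x$pos < segment[2]
  if (!any(sel_donor)) {
    return(list(data = x,
                truth = data.frame(assembled_chrom = character(),
                                   assembled_pos = integer(),
                                   true_chrom = character(),
                                   true_pos = integer())))
  }
  truth <- data.frame(assembled_chrom = source_chrom,
                      assembled_pos = as.integer(segment[1] +
                                                 (x$pos[sel_donor] - donor[1])),
                      true_chrom = target_chrom,
                      true_pos = x$pos[sel_donor])
  keep <- !sel_drop
  x$chrom[sel_donor] <- source_chrom
  x$pos[sel_donor] <- truth$assembled_pos
  x$chrom <- x$chrom[keep]
  x$pos <- x$pos[keep]
  x$geno <- x$geno[keep, , drop = FALSE]
  if (!is.null(x$pos_cm)) x$pos_cm <- x$pos_cm[keep]
  ## restore sorted order on the assembled coordinates
  o <- order(x$chrom, x$pos)
  x$chrom <- x$chrom[o]; x$pos <- x$pos[o]
  x$geno <- x$geno[o, , drop = FALSE]
  if (!is.null(x$pos_cm)) x$pos_cm <- x$pos_cm[o]
  list(data = x, truth = truth)
}
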