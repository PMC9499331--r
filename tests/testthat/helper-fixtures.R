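# shared fixture builders; all data is generated in code

# toy variant table exercising the selection criteria
make_variant_table <- function() {
  geno <- rbind(
    c("0/0", "1/1", "0/0", "0/1", "1/1", "0/1"),   # clean diallelic site
    c("0/1", "1/1", "0/0", "0/1", "1/1", "0/1"),   # parent A heterozygous
    c("0/0", "1/1", "0/2", "0/1", "1/1", "2/2"),   # triallelic
    c("0/0", "1/1", "0/0", "0/0", "0/0", "0/1"),   # MAF below threshold
    c("1/1", "0/0", "1/1", "0/1", "0/0", "0/1"))   # parents swapped alleles
  colnames(geno) <- c("PA", "PB", "F1", "F2", "F3", "F4")
  structure(list(chrom = rep("c1", 5), pos = c(100L, 200L, 300L, 400L, 500L),
                 ref = rep("A", 5),
                 alt = c("G", "G", "G,T", "G", "G"),
                 geno = geno),
            class = "variant_table")
}

# variant table whose F2 codes reproduce a marker matrix (parents added),
# used to check that marker selection is idempotent
rebuild_variant_table <- function(mm) {
  code2gt <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(mm$geno), ncol(mm$geno),
               dimnames = dimnames(mm$geno))
  ok <- !is.na(mm$geno)
  gt[ok] <- code2gt[mm$geno[ok] + 1L]
  gt <- cbind(PA = "0/0", PB = "1/1", gt)
  structure(list(chrom = mm$chrom, pos = mm$pos,
                 ref = rep("A", nrow(gt)), alt = rep("G", nrow(gt)),
                 geno = gt),
            class = "variant_table")
}

# independent brute-force bin partition: boundary wherever two consecutive
# anchor vectors differ (NA-free input)
brute_force_partition <- function(calls) {
  n <- nrow(calls)
  if (n == 1) return(rep(1L, 1L))
  brk <- vapply(2:n, function(a) any(calls[a, ] != calls[a - 1, ]),
                logical(1))
  cumsum(c(1L, as.integer(brk)))
}

# draw two-locus F2 genotype pairs at a given recombination fraction
draw_f2_pair <- function(r, n) {
  p <- matrix(c((1 - r)^2 / 4, r * (1 - r) / 2, r^2 / 4,
                r * (1 - r) / 2, ((1 - r)^2 + r^2) / 2, r * (1 - r) / 2,
                r^2 / 4, r * (1 - r) / 2, (1 - r)^2 / 4), 3, 3)
  cls <- sample(1:9, n, TRUE, as.vector(p))
  list(g1 = (cls - 1L) %% 3L, g2 = (cls - 1L) %/% 3L)
}

# window tracks object built directly from a call matrix (one chromosome)
toy_tracks <- function(calls, step = 1e4, chrom = "c1") {
  anchors <- seq(step, by = step, length.out = nrow(calls))
  structure(list(tracks = stats::setNames(list(
    list(anchors = anchors, gi = calls + 0, call = calls)), chrom),
    params = window_params(step = step)), class = "window_tracks")
}

# genetic map assembled by hand from a table of bins (single chromosome
# per lg unless stated); minimal fields used by downstream code
toy_map <- function(table, map_fun = "kosambi") {
  structure(list(table = table, map_fun = map_fun,
                 discordant = character(0), unplaced = character(0),
                 logs = list()),
            class = "genetic_map")
}
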