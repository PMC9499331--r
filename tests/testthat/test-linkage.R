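test_that("EM recombination fraction handles canonical cases", {
  set.seed(71)
  g <- sample(0:2, 400, TRUE, c(.25, .5, .25))
  # identical vectors: r = 0, strong linkage
  est <- estimate_rf(g, g)
  expect_equal(est$r, 0, tolerance = 1e-6)
  expect_gt(est$lod, 10)
  # independent bins: r ~ 0.5, LOD ~ 0
  pair <- draw_f2_pair(0.5, 1000)
  est2 <- estimate_rf(pair$g1, pair$g2)
  expect_lt(abs(est2$r - 0.5), 3 * sqrt(0.25 / (2 * 1000)))
  expect_lt(est2$lod, 2)
  # missing data: pairwise-complete, errors when nothing overlaps
  expect_error(estimate_rf(c(NA, NA, 0), c(1, 2, NA)), "at least 2")
})

test_that("EM estimate is unbiased at r = 0.10 and matches the grid oracle", {
  set.seed(72)
  rs <- replicate(500, {
    pair <- draw_f2_pair(0.10, 200)
    estimate_rf(pair$g1, pair$g2)$r
  })
  # ~2/3 of the Fisher information of 2n meioses is retained with
  # codominant F2 markers; 3 SE with the conservative full-information SE
  se <- sqrt(0.1 * 0.9 / (2 * 200)) / sqrt(500)
  expect_lt(abs(mean(rs) - 0.10), 3 * se * 1.5)

  for (i in 1:25) {
    pair <- draw_f2_pair(runif(1, 0.02, 0.45), sample(50:200, 1))
    em <- estimate_rf(pair$g1, pair$g2)$r
    grid <- rf_grid_search(pair$g1, pair$g2)
    expect_lt(abs(em - grid), 1e-4)
  }
})

test_that("mapping functions match closed forms and round-trip", {
  expect_equal(map_distance(0, "kosambi"), 0)
  expect_equal(map_distance(0, "haldane"), 0)
  expect_equal(map_distance(0.25, "haldane"), -50 * log(0.5))
  expect_equal(map_distance(0.25, "haldane"), 34.657359, tolerance = 1e-6)
  expect_equal(map_distance(0.25, "kosambi"), 25 * log(3))
  expect_equal(map_distance(0.25, "kosambi"), 27.465307, tolerance = 1e-6)
  r <- seq(0, 0.49, by = 0.01)
  for (fun in c("kosambi", "haldane")) {
    expect_equal(map_rf(map_distance(r, fun), fun), r, tolerance = 1e-10)
    d <- seq(0, 80, by = 5)
    expect_equal(map_distance(map_rf(d, fun), fun), d, tolerance = 1e-10)
  }
  # Kosambi compresses relative to Haldane
  expect_true(all(map_distance(r[-1], "kosambi") <=
                  map_distance(r[-1], "haldane")))
  expect_error(map_distance(0.5), "0.5")
  expect_error(map_rf(-1), ">= 0")
})

# small simulated bin set on one chromosome: true bin genotypes observed
# perfectly (bin-level calls), carrying known recombination structure
sim_bin_set <- function(n_bins, n_ind, length_cm, seed, chrom = "c1") {
  spec <- map_spec(data.frame(name = chrom, length_bp = n_bins * 1e5,
                              length_cm = length_cm))
  mp <- data.frame(chrom = chrom, pos = seq(5e4, by = 1e5,
                                            length.out = n_bins))
  f2 <- simulate_f2_genotypes(spec, n_ind, mp, seed = seed)
  ids <- sprintf("B%s_%d", gsub("\\D", "", chrom), seq_len(n_bins))
  if (!nzchar(gsub("\\D", "", chrom)))
    ids <- sprintf("B%s_%d", chrom, seq_len(n_bins))
  geno <- f2$geno
  rownames(geno) <- ids
  bins <- data.frame(bin_id = ids, chrom = chrom,
                     start = mp$pos - 5e4, end = mp$pos + 5e4,
                     anchor_first = mp$pos, anchor_last = mp$pos,
                     n_anchors = 1L)
  chi <- segregation_chi2(geno)
  bins <- cbind(bins, chi[, c("n0", "n1", "n2", "chi2", "kept")])
  list(bs = structure(list(bins = bins, geno = geno,
                           params = window_params()), class = "bin_set"),
       f2 = f2, spec = spec)
}

test_that("fixed-order map recovers simulated length and splits unlinked chains", {
  sim <- sim_bin_set(60, 200, 120, seed = 73)
  map <- build_fixed_order_map(sim$bs)
  expect_equal(length(unique(map$table$lg)), 1)
  len <- max(map$table$cm)
  expect_lt(abs(len - 120) / 120, 0.15)
  # cM non-decreasing in physical order
  expect_true(all(diff(map$table$cm) >= 0))

  # a chain with an unlinked junction splits into two groups
  simA <- sim_bin_set(20, 150, 40, seed = 74)
  simB <- sim_bin_set(20, 150, 40, seed = 75)
  geno <- rbind(simA$bs$geno,
                `rownames<-`(simB$bs$geno, sprintf("B_b%d", 1:20)))
  bins <- rbind(simA$bs$bins, transform(simB$bs$bins,
                                        bin_id = sprintf("B_b%d", 1:20),
                                        start = start + 2e6, end = end + 2e6))
  bs <- structure(list(bins = bins, geno = geno, params = window_params()),
                  class = "bin_set")
  map2 <- build_fixed_order_map(bs)
  expect_equal(length(unique(map2$table$lg)), 2)

  # perfectly linked chain: single LG of length 0
  g <- matrix(rep(sample(0:2, 50, TRUE, c(.25, .5, .25)), 5), 5, byrow = TRUE,
              dimnames = list(paste0("B_", 1:5), paste0("I", 1:50)))
  bins0 <- data.frame(bin_id = paste0("B_", 1:5), chrom = "c1",
                      start = (0:4) * 1e4, end = (1:5) * 1e4,
                      anchor_first = (0:4) * 1e4 + 5e3,
                      anchor_last = (0:4) * 1e4 + 5e3, n_anchors = 1L,
                      segregation_chi2(matrix(rep(0:2, c(12, 26, 12)),
                                              nrow = 1))[rep(1, 5), ])
  bs0 <- structure(list(bins = bins0, geno = g, params = window_params()),
                   class = "bin_set")
  map0 <- build_fixed_order_map(bs0)
  expect_equal(length(unique(map0$table$lg)), 1)
  expect_equal(max(map0$table$cm), 0)
  expect_true(all(map0$table$redundant[-1]))
})

test_that("rippling places an identical inquiry bin at its twin and flags unlinked bins", {
  sim <- sim_bin_set(30, 200, 60, seed = 76)
  bs <- sim$bs
  # clone bin 15 as an inquiry with off-chromosome physical coordinates
  clone <- bs$geno[15, , drop = FALSE]
  rownames(clone) <- "Bx_1"
  bs$geno <- rbind(bs$geno, clone)
  bs$bins <- rbind(bs$bins, transform(bs$bins[15, ], bin_id = "Bx_1",
                                      chrom = "c9", start = 1e4, end = 2e4))
  map <- build_fixed_order_map(structure(list(
    bins = sim$bs$bins, geno = sim$bs$geno, params = bs$params),
    class = "bin_set"))
  map2 <- ripple_place_discordant(map, bs, "Bx_1")
  tb <- map2$table
  i <- which(tb$bin_id == "Bx_1")
  expect_equal(tb$cm[i], tb$cm[tb$bin_id == bs$bins$bin_id[15]])
  expect_true(tb$redundant[i] || tb$redundant[which(tb$bin_id == bs$bins$bin_id[15])])
  expect_true(tb$relocated[i])

  # an unlinked inquiry stays unplaced
  set.seed(77)
  rnd <- matrix(sample(0:2, 200, TRUE, c(.25, .5, .25)), 1,
                dimnames = list("Bz_1", colnames(sim$bs$geno)))
  bs$geno <- rbind(bs$geno, rnd)
  bs$bins <- rbind(bs$bins, transform(bs$bins[1, ], bin_id = "Bz_1",
                                      chrom = "c9", start = 5e4, end = 6e4))
  map3 <- ripple_place_discordant(map, bs, "Bz_1")
  expect_true("Bz_1" %in% map3$unplaced)
  expect_false("Bz_1" %in% map3$table$bin_id)
})

test_that("correction fixes lone double recombinants and merging is idempotent", {
  sim <- sim_bin_set(12, 150, 6, seed = 78)  # tightly linked chain
  bs <- sim$bs
  map <- build_fixed_order_map(bs)
  # plant a 0,2,0 double-recombinant pattern across three tight bins
  ord <- map$table$bin_id
  mid <- ord[6]
  vic <- which(bs$geno[ord[5], ] == 0L & bs$geno[ord[7], ] == 0L &
               bs$geno[mid, ] == 0L)[1]
  expect_false(is.na(vic))
  bs$geno[mid, vic] <- 2L
  res <- correct_and_merge(build_fixed_order_map(bs), bs)
  expect_equal(unname(res$bins$geno[mid, vic]), 0L)
  expect_gte(res$n_corrections, 1)

  # two physically consecutive bins at r = 0 merge into one
  g2 <- bs$geno[1:2, ]
  g2[2, ] <- g2[1, ]
  bs2 <- bs
  bs2$geno[2, ] <- g2[2, ]
  res2 <- correct_and_merge(build_fixed_order_map(bs2), bs2)
  expect_lt(nrow(res2$bins$bins), nrow(bs2$bins))
  merged_id <- bs2$bins$bin_id[1]
  expect_equal(res2$bins$bins$end[res2$bins$bins$bin_id == merged_id],
               bs2$bins$end[2])

  # clean, distinguishable data: a fixpoint in one pass, nothing changed
  simc <- sim_bin_set(8, 200, 40, seed = 79)
  resc <- correct_and_merge(build_fixed_order_map(simc$bs), simc$bs)
  res_again <- correct_and_merge(resc$map, resc$bins)
  expect_equal(res_again$n_corrections, 0)
  expect_equal(res_again$n_merged, 0)
  expect_equal(res_again$map$table, resc$map$table)
})

test_that("map summary implements the effective-bin and coverage arithmetic", {
  # synthetic map mirroring published totals: 3776 bins, 132 redundant,
  # physical span 1058.80 Mb of a 1073.14 Mb genome
  n <- 3776
  cm <- cumsum(c(0, rep(0.5, n - 1)))
  red <- rep(FALSE, n); red[sample(2:n, 132)] <- FALSE
  # force exactly 132 redundant positions
  cm[2:133] <- cm[1]
  tab <- data.frame(lg = "LG1", bin_id = sprintf("B_%d", 1:n), chrom = "E",
                    phys_start = seq(0, by = 280000, length.out = n),
                    phys_end = seq(0, by = 280000, length.out = n) + 251500,
                    cm = sort(cm), redundant = FALSE, relocated = FALSE)
  tab$redundant <- c(FALSE, diff(tab$cm) < 1e-9)
  tab$phys_start[1] <- 0
  tab$phys_end[n] <- 1058.80e6
  s <- map_summary(toy_map(tab), c(E = 1073.14e6))
  tot <- s[s$lg == "Total", ]
  expect_equal(tot$n_bins, 3776)
  expect_equal(tot$n_effective, 3776 - 132)
  expect_equal(tot$n_effective, 3644)
  expect_equal(tot$coverage_pct, 98.66)

  # single-bin LG: spacing undefined, span equals the bin extent
  tab1 <- data.frame(lg = "LG2", bin_id = "B_x", chrom = "F",
                     phys_start = 1e6, phys_end = 2e6, cm = 0,
                     redundant = FALSE, relocated = FALSE)
  s1 <- map_summary(toy_map(tab1), c(F = 10e6))
  expect_true(is.na(s1$spacing_nominal[1]))
  expect_equal(s1$span_mb[1], 1)
  expect_equal(s1$coverage_pct[1], 10)
})

test_that("RGP profile recovers piecewise slopes and is exact when linear", {
  # perfectly linear: every region slope equals the global RGP
  tab <- data.frame(lg = "c1", bin_id = sprintf("B_%d", 1:40), chrom = "c1",
                    phys_start = seq(0, 39e6, by = 1e6),
                    phys_end = seq(1e6, 40e6, by = 1e6),
                    cm = seq(0.5, 39.5, by = 1) * 2.5,  # 2.5 cM/Mb
                    redundant = FALSE, relocated = FALSE)
  prof <- rgp_profile(toy_map(tab))
  expect_true(all(abs(prof$rgp - 2.5) < 1e-6))

  # three-slope structure (5, 0.2, 6) recovered within 20%
  x <- seq(0.5, 79.5, by = 1)  # Mb midpoints over an 80 Mb chromosome
  slope <- function(p) ifelse(p < 15, 5, ifelse(p < 65, 0.2, 6))
  y <- cumsum(slope(x) * 1)
  set.seed(80)
  tab3 <- data.frame(lg = "c1", bin_id = sprintf("B_%d", seq_along(x)),
                     chrom = "c1", phys_start = (x - 0.5) * 1e6,
                     phys_end = (x + 0.5) * 1e6,
                     cm = y + rnorm(length(y), 0, 0.3),
                     redundant = FALSE, relocated = FALSE)
  prof3 <- rgp_profile(toy_map(tab3))
  expect_equal(nrow(prof3), 3)
  expect_lt(abs(prof3$rgp[1] - 5) / 5, 0.2)
  expect_lt(abs(prof3$rgp[2] - 0.2), 0.2)  # absolute slack near zero
  expect_lt(abs(prof3$rgp[3] - 6) / 6, 0.2)
  # region boundaries near the true breaks
  expect_lt(abs(prof3$end_mb[1] - 15), 5)
  expect_lt(abs(prof3$end_mb[2] - 65), 5)
})

test_that("simulated genome-wide pipeline respects the monotone cM invariant", {
  sim <- sim_bin_set(40, 120, 80, seed = 81)
  built <- build_map(sim$bs)
  tb <- built$map$table
  for (lg in unique(tb$lg))
    expect_true(all(diff(tb$cm[tb$lg == lg]) >= -1e-12))
})
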