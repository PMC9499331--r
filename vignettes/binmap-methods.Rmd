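---
title: "Recombination bin maps from low-depth F2 resequencing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recombination bin maps from low-depth F2 resequencing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binmapf2)
```

# The problem

Whole-genome resequencing of a mapping population at very low depth (~2
reads per site per individual) yields millions of markers but unreliable
individual genotype calls. In an F2 intercross the damage is concentrated
on heterozygotes: with `k` reads drawn independently from the two alleles,
a heterozygote shows only one allele -- and is miscalled homozygous -- with
probability

$$p_m = 2 \cdot (1/2)^k = 1/2^{k-1},$$

which is 1 at 1x, 1/2 at 2x, and only drops below 1/16 beyond 5x. At the
economical ~2x depth, half of all heterozygous genotypes are wrong, so
marker-by-marker linkage analysis is hopeless. `binmapf2` implements a
window-and-bin strategy for exactly this regime, together with the
downstream linkage-map construction and QTL analysis on F2:3 line means.

The observed proportion of heterozygous calls per individual (PHG) gives a
direct diagnostic: a true F2 is 50% heterozygous, so at depth `k` one
expects $p_o = 0.5\,(1 - 1/2^{k-1})$, i.e. 0.25 at 2x.
`compute_individual_qc()` reports both the observed and expected value.

# Pipeline overview

1. **Marker selection** (`select_markers()`): diallelic variants,
   homozygous in parent A, F2 minor allele frequency at least 0.3 (allele
   counts over non-missing genotypes). We additionally require parent B
   homozygous for the alternate allele so that codes 0/2 are anchored
   unambiguously in both parents; sites excluded by this rule are counted
   in the `excluded` attribute. Genotypes are coded 0 (parent-A
   homozygote), 1 (het), 2 (parent-B homozygote).
2. **Window genotype index** (`window_scan()`): for each individual, GI =
   $0 p_0 + 1 p_1 + 2 p_2$ over the markers in a 300 kb window sliding in
   10 kb steps. Because a miscalled het falls to either homozygote with
   equal probability, GI averages out the errors: it sits near 1 in het
   regions and near 0/2 in parental regions. Calls: GI <= 0.2 is 0,
   0.2 < GI <= 1.8 is 1, GI > 1.8 is 2; windows with fewer than 10
   non-missing markers are NA.
3. **Bin partition** (`partition_bins()`): maximal runs of consecutive
   anchors whose population call vectors co-segregate completely become
   recombination bins; bins with segregation chi-square above 25 (1:2:1
   test on 2 df, p < 1e-5) are dropped.
4. **Linkage map** (`build_map()`): adjacent-bin recombination fractions
   by an F2 EM estimator, bins fixed in reference order, discordant
   bins/blocks peeled and re-placed by rippling, then iterative genotype
   error correction and merging of co-positioned physically consecutive
   bins.
5. **QTL scan** (`interval_mapping_scan()`): Haley-Knott regression of
   F2:3 line means on expected additive/dominance codings from flanking
   bins, with genome-wise LOD thresholds from phenotype permutations
   (`permutation_threshold()`), peak calling, cross-season combination,
   a naive per-marker association cross-check (`association_scan()`), and
   candidate-variant filtering inside a QTL interval
   (`candidate_variant_filter()`).

# Statistical models and numerical choices

## Sequencing model

`apply_sequencing_model()` draws a depth per marker per individual (fixed
`k` or Poisson(lambda); the field rarely reports the per-marker depth
distribution, so both are exposed and fixed-depth is the default in our
validations). Depth 0 yields NA. Heterozygotes are called from the set of
read alleles; homozygotes are read correctly unless a per-read
`base_error` is set. The implied het miscall probability is exactly
$1/2^{k-1}$, which the test suite verifies against Monte Carlo for
k = 1..8.

## Recombination fraction EM

For two codominant F2 markers the nine genotype classes are multinomial
with probabilities determined by r; the double-heterozygote class mixes
coupling and repulsion phases, so its expected recombinant-gamete count,
$2r^2 / ((1-r)^2 + r^2)$, is imputed iteratively (`estimate_rf()`,
tolerance 1e-12 on r, start 0.25). LOD is the log10 likelihood ratio
against r = 0.5. An independent 1e-4 grid search over the same likelihood
(`rf_grid_search()`) is kept in the package purely as a cross-check and is
compared with the EM on random instances in the tests.

## Mapping function

Kosambi is the default (the common default of interval-mapping software in
this field); Haldane is selectable. For chaining adjacent bins, r is
capped at 0.4999 so that an unlinked junction produces a large finite
distance that trips the split rule rather than an infinity.

## Fixed order, discordance and rippling

Bin order within a chromosome is fixed by the reference coordinates;
linkage groups are split where an adjacent distance exceeds 50 cM or the
linkage LOD falls below 3. Two discordance triggers feed the rippling
queue:

* a single interior bin whose insertion inflates the local map length by
  more than 10 cM relative to skipping it;
* a block of up to 10 consecutive bins delimited by two adjacent distances
  above 15 cM, when skipping the whole block saves more than 10 cM.

The block rule exists because a mis-assembled segment produces several
consecutive bins that are tightly linked *to each other* but not to their
physical neighbours -- skipping any single one of them saves nothing, so a
single-bin test cannot see the problem (we observed exactly this failure
mode in simulation before adding the rule). A rippled bin is inserted
beside its most tightly linked target (minimum r among mapped bins with
LOD >= 6) on the side that adds the least map length; bins without a
qualifying target are left unplaced and logged, mirroring how a real study
reports unmappable bins.

## Error correction and merging

`correct_and_merge()` iterates to a fixpoint: (i) a genotype implying a
double recombination around a single bin within 5 cM, with agreeing
flanks, is replaced by the flanking genotype (under no interference a
double crossover inside 5 cM has probability ~6e-4, far below the 2x
window miscall rate); missing bin genotypes are imputed from agreeing
flanks; (ii) physically consecutive bins at identical cM positions merge
(union extent, consensus genotypes, first id kept); (iii) linkage is
re-estimated. Each pass either changes something or stops, and a safety
cap of 25 passes bounds the loop.

## Map summaries

`map_summary()` reports per linkage group and in total: length, bin count,
effective bins (total minus redundant, where a bin is redundant iff its cM
position equals its predecessor's within 1e-9), nominal and effective mean
spacing (total length over total adjacent gaps), physical span and
coverage. For a chromosome split across linkage groups the per-LG coverage
is undefined (NA) and the chromosome is counted once in the totals; how
published tables apportion "full length" to chromosome segments is not
recoverable, so we document this convention and test it for
self-consistency. `rgp_profile()` fits a continuous piecewise-linear
genetic-vs-physical curve by least squares over breakpoint candidates on
the bin grid, choosing between two and three segments by BIC: three
segments capture the common high-low-high recombination pattern (distal
regions I/III vs the suppressed pericentromeric region II); two cover
chromosomes lacking a terminal region.

## QTL analysis

Interval mapping is Haley-Knott regression, deliberately cofactor-free: a
single-QTL scan is the appropriate tool for the major-QTL setting this
package validates, and stepwise-cofactor machinery (as in composite
methods) is out of scope. F2:3 line means estimate the F2 parent's
genotypic value, so the dominance coding for a heterozygous F2 parent is
1/2 (its F3 family segregates 1:2:1 and the family mean carries d/2).
Ordinal scores are analyzed as numeric line means. LOD =
(n/2) log10(RSS0/RSS1); PVE = 100 (1 - RSS1/RSS0) at the peak. The scan
grid is 1 cM plus every bin position, so the scan at a fully observed bin
reduces exactly to the single-bin regression (tested). A negative additive
effect means the code-2 (wild-parent) allele decreases the trait.
Permutation thresholds take the (1 - alpha) quantile of genome-wide
maximum LOD over seeded phenotype permutations; the scan over permutations
is vectorized through per-position QR decompositions.

# What the generator emulates -- and what it does not

`default_map_spec()` fixes the synthetic study conditions: 3 chromosomes
of 80 Mb / 150 cM with a three-region structure (15/70/15% of physical
length at relative recombination weights 5 : 0.3 : 5 and marker densities
3 : 1 : 3), 20,000 markers, 200 F2 individuals, fixed sequencing depth 2
-- the size, depth and genome organisation typical of an eggplant-scale
bin-mapping study. Meiosis is a no-interference Poisson process
(crossover count ~ Poisson(L/100), positions uniform), the simplest model
consistent with mapping-function use; QTL effects follow the standard F2
parameterization with residual-sd-scaled Gaussian line-mean noise; an
optional distortion knob resamples individuals carrying a chosen genotype
at a chosen locus; `simulate_misassembly()` relocates a donor segment's
markers onto another chromosome's coordinates while keeping their genetic
linkage, with a truth record.

Passing tests on these simulations show that the pipeline recovers what
the generator encodes: Mendelian segregation, Poisson crossovers, iid
read sampling, and a single major QTL. Real data add features the
generator does not model -- reference errors beyond clean segment swaps,
depth correlated along the genome and between individuals, allele-biased
capture, crossover interference, polygenic trait backgrounds -- so the
validations here bound implementation correctness, not field performance.

# Validation scales

The heavier checks run at deliberately chosen scales: map-length and
bin-accuracy recovery once at the full default scale (3 x 150 cM, n = 200,
20k markers, ~1500 bins); QTL-recovery (50 replicates) and mis-assembly
relocation (10 seeds) on 2-chromosome, 40 Mb / 100 cM genomes with 6-8k
markers; the null false-positive experiment on 200 replicates with 200
permutations each; and the genome-wise threshold band on a 14-linkage-group
map totalling ~2000 cM, the scale at which a 3-5 LOD threshold is the
expected order for n = 172 (on toy genomes the threshold is intrinsically
lower because fewer independent tests are scanned).

# Known limitations

* Marker order is never estimated de novo; everything rests on the
  reference order except rippling insertions.
* The association scan is a plain linear model, adequate for co-location
  checks in an F2 (where kinship is homogeneous), not a substitute for a
  mixed-model GWAS in structured material.
* Candidate-variant filtering computes codon changes only for SNPs with
  supplied codon context; other variants are flagged indeterminate rather
  than guessed.
* Ordinal traits are treated as quantitative line means throughout.

# A minimal worked run

```{r example, eval = FALSE}
spec <- default_map_spec(n_chrom = 2, length_bp = 4e7, length_cm = 100)
mp  <- sample_marker_positions(spec, 8000, seed = 1)
f2  <- simulate_f2_genotypes(spec, 200, mp, seed = 2)
mm  <- apply_sequencing_model(f2, depth_model("fixed", 2), seed = 3)
res <- bin_map_pipeline(mm, window_params(), chrom_lengths(spec))
map_summary(res$map, chrom_lengths(spec))

q  <- qtl_spec("chr02", 63, a = -1.9, d = 0, residual_sd = 1, mu = 3)
ph <- simulate_f23_phenotypes(f2, q, lines = f2$individuals[1:172],
                              trait = "LVC", seed = 4)
cur <- interval_mapping_scan(res$map, res$bins, ph)
thr <- permutation_threshold(res$map, res$bins, ph, n_perm = 1000, seed = 5)
call_peaks(cur, thr, res$map)
```
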