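Package: binmapf2
Title: Recombination Bin Maps and QTL Mapping from Low-Depth Sequenced F2 Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs recombination bin-based genetic linkage maps from
    low-depth whole-genome-resequencing genotypes of an F2 intercross and maps
    quantitative trait loci (QTL) on the bin map from F2:3 line means. The
    pipeline selects diallelic markers polymorphic between the two parents,
    computes a sliding-window genotype index that absorbs the heterozygote
    miscalls characteristic of ~2x sequencing depth, partitions each chromosome
    into co-segregating recombination bins, estimates recombination fractions by
    an EM algorithm for codominant F2 data, builds fixed-order linkage groups
    with rippling-based placement of discordant bins and iterative genotype
    error correction, and performs Haley-Knott interval mapping with
    permutation-based LOD thresholds. A synthetic F2/F2:3 generator with an
    explicit read-sampling depth model supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
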