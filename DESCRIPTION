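Package: admrscan
Title: Regional Age-EWAS of MeDIP-seq Methylomes Within GWAS LD Blocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: A tested pipeline for detecting age-associated differentially
    methylated regions (a-DMRs) in sliding-window MeDIP-seq methylomes
    restricted to the linkage-disequilibrium blocks of GWAS catalogue SNPs.
    Builds LD blocks from a recombination map (10 cM/Mb hotspot boundaries),
    enumerates 500-bp/250-bp-slide windows, fits per-window linear mixed
    models (age, haplotype-tagging SNP allelic count, smoking, batch and
    leukocyte-fraction fixed effects; family and twin-pair random
    intercepts) with likelihood-ratio tests and Bonferroni control, merges
    significant windows into directional a-DMRs, and provides
    cell-composition negative controls (monozygotic-discordant blood-cell
    EWAS), region-set enrichment against LD-block background windows,
    genotype-by-age interaction testing, replication concordance, and a
    synthetic twin-cohort generator with planted effects for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
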