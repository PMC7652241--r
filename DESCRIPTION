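Package: trisexscan
Title: Sex-Linkage, Differentiation and Recombination Analysis for
    Three-Sex-Chromosome Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing species in which three sex chromosome types
    (W, Z and Y) co-segregate, as in the Western clawed frog. Provides the
    cross/segregation model for all six parental genotype combinations,
    synthetic generators for RAD-style family genotype data and gonadal
    RNA-seq counts with gametolog divergence, a family genotype quality-control
    cascade, a parent-of-origin sex-linkage association scan with
    double-recombinant genotyping-error masking, between-sex Weir-Cockerham
    FST sliding-window scans with autosomal resampling bands, within-individual
    nucleotide-diversity inference of sex-chromosome genotypes including
    Y-origin inference, sex-biased-expression region enrichment statistics,
    and sex-specific linkage maps with crossover localisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
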