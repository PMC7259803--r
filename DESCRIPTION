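Package: ploidpop
Title: Ploidy, Inheritance Mode and Population-Genetic Analysis of Polyploid Taxa
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing polyploid species complexes from targeted
    sequencing data: ploidy assignment from allele frequency distributions at
    biallelic sites via fixed-mean Gaussian mixture likelihood ratios,
    inference of tetrasomic versus disomic inheritance by constructing
    in-silico tetraploids from diploid read counts and comparing
    intermediate/rare allele-frequency ratios with Wilcoxon tests, locus-wise
    population-genetic summary statistics (nucleotide diversity, Watterson's
    theta, Tajima's D, dxy, Hudson's Fst) on phased haplotype alignments,
    gene-tree-space conflict analysis (Robinson-Foulds distances, MDS,
    PAM clustering with the gap statistic, gene concordance factors, a
    within-locus consistency resampling test), and habitat-suitability
    area-change statistics correlated with demographic summaries. Includes
    seeded synthetic-data generators (read counts under diploid, triploid and
    tetraploid genotype models with tetrasomic or two-subgenome disomic
    structure, neutral coalescent locus alignments, gene-tree mixtures,
    suitability raster pairs) so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    cluster,
    graphics,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
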