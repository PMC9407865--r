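Package: ripkit
Title: Detection and Population Analysis of Retrotransposon Insertion Polymorphisms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for discovering retrotransposon insertion polymorphisms (RIPs)
    between a bait gene locus and assembly-derived locus sequences, classifying
    insertions against a repeat consensus library (family, strand, identity, target
    site duplication), and analysing their population genetics (allele and genotype
    frequencies, Hardy-Weinberg equilibrium, polymorphic information content),
    genotype-phenotype associations (one-way ANOVA with Tukey HSD and compact letter
    displays), and expression consequences (2^-ddCt relative expression and
    dual-luciferase relative reporter activity). Includes a seeded synthetic-data
    generator that plants SINE-like insertions with target site duplications into
    simulated loci so every stage is testable without external genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
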