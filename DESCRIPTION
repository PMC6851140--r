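Package: sexlinkr
Title: Sex-Linked Marker Discovery from Reduced-Representation Genotyping Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers sex-linked SNP and restriction-fragment presence/absence
    markers in DArTseq-style genotype tables, infers the heterogametic sex
    determination system (XX-XY versus ZZ-ZW), estimates the expected number of
    spuriously sex-linked loci, genotypically sexes individuals of unknown
    phenotypic sex, and profiles per-male heterozygosity over moderately
    sex-linked loci to detect differentiated Y-chromosome lineages. Includes
    population-structure support statistics (pairwise Fst, Nei genetic distance
    between individuals, principal coordinates analysis) and a synthetic-data
    generator that emulates the structure of a wild population with a
    male-heterogametic sex-determining region, a partially recombining
    pseudoautosomal region, and a feminised-Y male lineage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pheatmap
Config/testthat/edition: 3
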