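Package: bgcarch
Title: Module-Architecture Analysis of PKS and NRPS Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the in-silico comparison of modular polyketide synthase
    (PKS) and nonribosomal peptide synthetase (NRPS) biosynthetic gene clusters
    from their domain-organization notation. Provides a parser and serializer
    for the compact assembly-line notation (modules separated by "-", domains
    by "/", acyltransferase and adenylation specificities as subscripts),
    cluster typing (type-I/II/III PKS, NRPS, hybrid), co-linearity-based
    product-skeleton prediction, global module-architecture alignment for
    ortholog and module-indel detection, cross-genome conserved-cluster
    inventory comparison, threshold-based genomospecies delimitation (gyrB
    identity and digital DNA-DNA hybridization), and seeded generators of
    synthetic assembly lines with known ground truth. Ships the cluster
    inventories of two marine Micromonospora strains and the quinolidomicin
    reference architecture as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
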