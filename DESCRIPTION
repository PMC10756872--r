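Package: pedexome
Title: Family-Based Prioritization of Exome Variants in Non-Syndromic
    Tooth Agenesis
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reusable pipeline for prioritizing candidate variants from
    family-based whole-exome sequencing of non-syndromic tooth agenesis
    cohorts. Builds patient subgroups from pedigrees (multiplex families
    and a pooled sporadic group), tests per-variant allele frequencies
    against a control cohort with a two-sided Fisher exact test and an
    odds-ratio gate, applies an annotation cascade (SnpEff impact class,
    SIFT/PolyPhen damaging-prediction or Asian minor-allele-frequency
    rescue for MODERATE variants, and gene-phenotype ontology gating),
    scores Mendelian segregation under dominant/recessive models, joins
    LOEUF constraint and ortholog-alignment conservation evidence, and
    performs hypergeometric gene-set enrichment after one-hop
    protein-protein-interaction neighbor expansion. Ships a seeded
    synthetic pedigree-cohort generator with planted causal variants and
    gate-specific decoys, plus a built-in nine-family study fixture, so
    every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    igraph,
    vcfR,
    yaml
Suggests:
    fgsea,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
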