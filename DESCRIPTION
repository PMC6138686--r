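Package: phenoloci
Title: Phenotype-Locus Association Networks from Patient CNV Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds tripartite phenotype-patient-locus networks from cohorts
    of patients carrying de novo copy number variants (CNVs) annotated with
    Human Phenotype Ontology (HPO) terms. Loci are derived as maximal genomic
    segments covered by a constant set of patient CNVs (small overlapping
    regions), patient phenotype annotations are propagated up the ontology,
    and each phenotype-locus pair is scored with the Hypergeometric Index
    (minus log10 of the upper-tail hypergeometric probability of the observed
    patient overlap). Fitted networks rank candidate phenotypes for novel
    clinical CNV cases with penetrance, percent-of-maximum and locus-overlap
    annotations, and a seeded synthetic-cohort generator with planted
    associations supports end-to-end validation without access-controlled
    patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
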