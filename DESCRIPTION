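Package: cpmland
Title: Fitness Landscapes, Cancer Progression Model DAGs, and Their Many-to-Many Relationship
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how well directed acyclic graphs (DAGs) of
    restrictions, the output of cancer progression models, can represent
    the fitness landscapes on which tumors evolve.  Provides complete
    genotype-fitness maps over biallelic loci with accessibility,
    fitness-peak and epistasis-square analysis; DAGs of restrictions with
    conjunctive (AND) semantics, transitive reduction and edge distances;
    random landscape generators (DAG-derived representable and
    non-representable families, Rough Mount Fuji); a continuous-time
    clonal birth-death tumor simulator with density-dependent death and
    stochastic size-dependent detection; a baseline conjunctive DAG
    learner; genotype misprediction metrics (proportions of false and
    negative discoveries), DAG diversity and variability summaries; and a
    landscape-matching loop that searches for landscapes reproducing the
    genotype frequencies of an observed cross-sectional cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
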