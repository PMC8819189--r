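Package: macetrait
Title: Pooled Root-Morphotype Tag Transcriptomics for Trait Candidate Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of a pooled forward-genetics
    transcriptomics workflow for root morphology traits: 3'-tag (MACE-style)
    read cleanup, fractional counting of multi-mapping reads, the MA-plot
    random-sampling (MARS) differential expression statistic for un-replicated
    library pairs, Venn-intersection selection of root-volume and root-length
    candidate genes, GO term enrichment with DAG level assignment, and
    efficiency-corrected qPCR validation against single-plant phenotypes.
    Includes a synthetic-data generator that reproduces the statistical
    structure the analysis assumes (multinomial tag sampling, pooled
    libraries, planted effector genes) with ground truth for recovery tests.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    nortest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
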