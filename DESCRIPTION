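Package: comod
Title: Disease-Associated Co-Expression Modules in GO-Defined Gene Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Discovers disease-associated gene co-expression modules inside
    Gene Ontology biological-process gene sets. For each GO term a weighted
    (soft-thresholded) Pearson correlation network is built, genes are
    clustered on topological-overlap dissimilarity into modules with
    eigengene and kME (module membership) summaries, and modules are carried
    through a two-step evaluation: eigengene-trait association with FDR
    control in a training cohort, then permutation Z_summary preservation in
    an independent testing cohort. Preserved, trait-associated modules are
    tested for hypergeometric enrichment in candidate-gene evidence sets
    (eQTL, copy-number, mutation, prognostic), overlapping candidates are
    merged by Fisher's exact test, and transcription-factor / microRNA
    target enrichment ranks putative regulators. A two-cohort synthetic data
    generator with planted latent-factor modules makes the whole pipeline
    testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, limma, igraph, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
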