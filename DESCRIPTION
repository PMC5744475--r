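Package: dryseedr
Title: Dry-Seed Dormancy Transcriptome Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for stored-mRNA transcriptome changes in dry,
    dormant and after-ripened seeds. Provides empirical-Bayes moderated-t
    differential abundance testing for two-group contrasts with
    Benjamini-Hochberg false discovery rate control, logFC-distribution
    skewness (adjusted Fisher-Pearson G1), seed-specific TAGGIT ontology
    profiling with a random-geneset control, transcription-factor family
    counting and TF-target enrichment with a minimum-hit cutoff and
    Benjamini-Yekutieli correction, generic term overrepresentation with
    observed-versus-expected reporting, direction-aware overlap between
    regulated gene sets, an mRNA half-life decay simulator for dry storage
    with stability-association binning, delta-delta-Ct qPCR relative
    quantification with Holm-corrected pairwise tests, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
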