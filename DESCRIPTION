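Package: stressmem
Title: Classification of Transcriptional Stress-Memory Genes from
    Repeated-Stress Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and classifies transcriptional stress-memory genes
    from gene-by-sample FPKM expression matrices collected under a
    repeated-stress design (control, first stress, recovery, second
    stress). Implements two-contrast differential-expression calling with
    an expression-floor filter, the nine-way memory taxonomy built from
    paired direction calls, summary and Venn-overlap accounting,
    cross-species ortholog memory-conservation analysis, hypergeometric
    term enrichment, delta-delta-Ct relative quantification with
    persistence testing, and physiological indices (relative water
    content, water-loss curves). A synthetic-data generator with planted
    memory classes makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    limma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
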