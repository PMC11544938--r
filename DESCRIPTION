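Package: isohybrid
Title: Hybrid Long- and Short-Read Transcriptome Characterization and
    Differential Splicing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for combined second- and third-generation
    transcriptome characterization: classification of long reads into
    full-length non-chimeric, full-length chimeric and non-full-length
    categories; collapse of redundant spliced isoforms; SQANTI-style
    eight-way structural annotation against a reference; ORF prediction
    with completeness classes and lncRNA calling; alternative splicing,
    alternative polyadenylation and fusion-transcript event detection;
    and hybrid splice-variant quantification with the exon inclusion
    statistic phi, delta-phi and FDR-based differential splicing calls.
    Ships a fully specified synthetic-data generator (toy genome,
    annotation, long reads, two-condition junction counts with planted
    effects) so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
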