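Package: lnckit
Title: Long Noncoding RNA Discovery and Temperature-Course Coexpression
    Analysis for De Novo Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis toolkit for de novo assembled plant
    transcriptomes profiled across an ordered temperature course. Identifies
    long noncoding RNAs with a multi-stage filter cascade (protein annotation,
    length, dual coding-potential scores, ORF size, structural-ncRNA triage),
    classifies temperature-course expression patterns into up/down/maintain
    classes, calls differentially expressed genes with a transparent
    noise-dominance probability, links lncRNAs and transcription factors to
    protein-coding targets through Pearson-correlation coexpression networks,
    and tests term enrichment with the hypergeometric distribution. A
    synthetic-data module generates transcript sets, annotation-hit tables and
    replicated FPKM matrices with planted ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
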