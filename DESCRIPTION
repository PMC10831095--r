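Package: taxsieve
Title: Taxonomy-Aware Detection and Removal of Contaminant Contigs from Annotated Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and removes contaminating sequences from annotated genome
    assemblies. Each predicted protein is classified taxonomically from a
    ranked homology hit list against a taxonomy-aware reference database, the
    hit list is trimmed to the top-scoring run of hits agreeing with the best
    hit's taxon, per-protein calls are aggregated into contig-level consensus
    votes, and contigs whose consensus contradicts the expected lineage of the
    query genome are removed together with all encoded proteins. Horizontally
    transferred genes integrated into host contigs are spared because they are
    outvoted by their chromosomal context. Includes spike-in benchmark
    machinery: a deterministic mock reference generator, synthetic
    contamination mixes on virtual contigs, ROC/AUC evaluation, top-10 taxon
    support ratios, and a marker-based ground-truth contig filter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
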