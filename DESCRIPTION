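Package: komix
Title: Host-Microbiome Joint Functional Analysis in KEGG Orthology Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for joint functional analysis of 16S microbiome
    and host transcriptome data in a common KEGG Orthology (KO) coordinate
    system. Infers KO abundances from OTU count tables by 16S copy-number
    normalization and gene-content projection with per-OTU contribution
    accounting; runs a uniform precision-weighted, empirical-Bayes moderated
    differential analysis on OTU, genus, KO and expression tables with
    log-fold-change confidence intervals and a fold-change/p-value gate;
    projects host differential genes into KO space from a mapping file;
    scores KEGG pathway enrichment with the EASE modified Fisher statistic
    per omic and on the joint KO union; and deconvolutes enriched pathways
    into the contributing transcripts and taxa. Ships a synthetic-study
    generator with planted differential features and planted enriched
    pathways for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite,
    optparse,
    biomformat
Config/testthat/edition: 3
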