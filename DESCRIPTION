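Package: bisminer
Title: Discovery and Prevalence Analysis of Bacteroidales Injection System Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining Bacteroidales injection system (BIS) gene
    clusters from annotated genomes and for screening metagenomes and
    metatranscriptomes against the 18-protein BIS roster. Implements
    sheath-anchored genome neighborhood extraction, greedy centroid
    clustering at an amino-acid identity threshold, role annotation and
    architecture classification of candidate loci, per-sample coverage
    scoring of alignment hit tables, a gene cooccurrence network statistic,
    donor-level prevalence aggregation, and percentile-bootstrap comparisons
    of group medians with Wilcoxon rank-sum validation. A synthetic-data
    module generates genomes with planted loci, cohorts with donor
    structure and planted group effects, alignment hit tables, and
    taxonomic profiles so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
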