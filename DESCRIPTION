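Package: icsmine
Title: Genome Mining and Evolution of Isocyanide Synthase Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for mining fungal genomes for isocyanide-synthase (ICS)
    biosynthetic gene clusters and analysing their evolution. Detects ICS
    backbone genes from protein-domain tables, calls cluster borders from
    shared promoter motifs, groups clusters into gene cluster families with an
    anchor-weighted composite distance, identifies biosynthetic cores and
    superfamilies, validates families with a BUSCO-anchored microsynteny
    conservation (linkage-disequilibrium) statistic, classifies dit1/dit2
    locus status, and compares gene trees with species trees. Ships a
    deterministic synthetic pangenome generator with planted truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    igraph,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
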