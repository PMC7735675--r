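Package: trimkit
Title: Multiple Sequence Alignment Trimming by Retention of
    Parsimony-Informative Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trims multiple sequence alignments by identifying and retaining
    parsimony-informative (and optionally constant) sites and by removing
    gap-rich sites, rather than by scoring and excising divergent regions.
    Provides five trimming strategies with a per-site audit log, readers and
    writers for eight alignment formats (FASTA, Clustal, MAF, XMFA, strict /
    sequential / relaxed PHYLIP, Stockholm) with automatic format detection,
    a command-line interface, tree-based evaluation utilities (normalized
    Robinson-Foulds distance, average bipartition support,
    desirability-based strategy ranking, bipartition-matched branch-length
    rank correlation), and a synthetic-alignment generator that designs
    columns with known classifications and simulates sequence evolution with
    insertions and deletions along a phylogeny.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
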