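Package: vdjrep
Title: Simulation and Analysis of B-Cell Receptor V(D)J Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for profiling B-cell receptor (BCR) immunoglobulin
    repertoires from heavy (IGH) and kappa light (IGK) chain variable-region
    sequences. Includes a ground-truth V(D)J rearrangement simulator with
    junctional P/N diversity, clonal lineage expansion and CDR-biased somatic
    hypermutation; a deterministic germline segment annotator with junction
    decomposition, CDR3 extraction and productivity calling; repertoire
    statistics (segment usage, V(D)J combination links with Circos export,
    CDR3 length and amino-acid composition, Shannon-Weaver diversity,
    rarefaction); clonotype and clone-lineage grouping with per-position
    somatic hypermutation profiles on a length-normalized 1..100 index and
    neighbor-joining clonal dendrograms; a between-sample lineage divergence
    odds score based on per-lineage Welch tests; and T20-style humanness
    scoring of antibody variable regions against a user-supplied human
    reference set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
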