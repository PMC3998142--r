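Package: sigscan
Title: Desk-Scale Protein Signature Scanning and Annotation Framework
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A dependency-driven job engine that runs pluggable
    scan/post-process analyzers over chunked protein sequence sets,
    integrates raw signature matches with entry, Gene Ontology and pathway
    annotation, caches precomputed matches by sequence checksum, translates
    nucleotide input through six-frame open reading frame discovery with
    coordinate back-mapping, and emits TSV, XML, GFF3 and JSON results.
    Ships built-in pattern and profile analyzers plus a seeded synthetic
    fixture generator with planted motifs, so the whole pipeline runs with
    no external binaries or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    digest,
    jsonlite,
    optparse,
    parallel,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
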