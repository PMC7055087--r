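Package: splitsv
Title: Structural Variant Calling from Low-Depth Long-Read Split Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and genotypes structural variants (deletions, insertions,
    tandem duplications, inversions, translocations and transpositions) from
    split alignments of long sequencing reads (ONT/PacBio) at low depth of
    coverage. Alignments in BLAST tabular, PAF or SAM dialects are normalised
    into per-read alignment profiles; novel adjacencies are detected and
    classified by a rule-based split-read algorithm, clustered into candidate
    calls, depth-annotated at each breakend, cleaned with a robust
    median/MAD outlier threshold, and scored with a small feed-forward
    neural network whose output is converted into a Phred-like confidence
    score. The package also bundles an SV-genome and long-read simulator
    with ground-truth tables, a breakend-window benchmarking module
    (precision/recall/F1 with repeat-family stratification), a VCF 4.2
    writer and an HTML/CSV run report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
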