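Package: mitoterm
Title: Mitochondrial 3' Terminome Profiling and Nonstop mRNA Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies nonstop messenger RNAs from 3'-end deep
    sequencing of the mitochondrial transcriptome. Reads from template-switching
    (TGIRT/R2R) libraries are adapter- and quality-trimmed, anchored by exact
    k-mer match onto the 3' coding sequence of each mitochondrial mRNA, and
    classified into 3'-end categories (CDS, CDS + poly(A), CDS + UTR, CDS +
    tRNA, truncated + poly(A)). Genome-aware translation-termination logic using
    the vertebrate mitochondrial genetic code (including poly(A)-completed UAA
    stops, tRNA-junction in-frame stops, and the release-factor-resistant AGA /
    AGG terminal codons) assigns each read a termination status, from which
    per-transcript category proportions, nonstop totals and 3'-position
    histograms are computed. Also includes a terminal-codon and -1 ribosomal
    frameshift codon census over sets of CDS 3'-end sequences, a bundled
    annotated human mitochondrial genome, and a ground-truth-labelled synthetic
    read simulator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
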