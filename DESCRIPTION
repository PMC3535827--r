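Package: consoligo
Title: Degenerate PCR Primer and Probe Design from Multiple Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs an IUPAC-degenerate consensus sequence from a
    multiple sequence alignment (or uses a single, possibly degenerate,
    sequence directly) and locates conserved PCR primers, real-time PCR
    primer/probe sets, or all valid oligos by sliding a product-size
    window along the consensus. Reports sequence, coordinates, degeneracy,
    GC-content range, Wallace-rule dissociation temperature range, and
    nearest-neighbor melting temperatures, as a tabulated text file.
    Includes a synthetic-alignment generator with planted conserved
    blocks and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
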