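Package: fragstitch
Title: Combinatorial Protein Backbone Assembly from Homologous Fragments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modular protein backbone design: segment homologous
    structures at conserved anchor positions, build torsion-space fragment
    conformation databases with a geometric graft-and-close acceptance gate,
    derive position-specific scoring matrix (PSSM) sequence constraints from
    filtered homolog alignments, combinatorially assemble new backbones onto a
    template with fixed catalytic residues, and rank design candidates with a
    fuzzy-logic product objective. Includes a synthetic toy-family generator so
    the full pipeline is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
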