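Package: InterfaceRegions
Title: Detection, Solvated Characterization and Family-Level Classification of
    Macromolecular Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects and physicochemically characterizes protein-protein,
    protein-peptide, protein-nucleic-acid and protein-saccharide interfaces in
    PDB-format structures, including water-mediated interactions. Typed
    molecular entities (domains, peptides, DNA/RNA units, oligosaccharides,
    waters) are derived from coordinates, connectivity and an editable
    chemistry dictionary; atomic contacts are classified as hydrogen bonds,
    salt bridges or van der Waals interactions by distance criteria.
    Interfaces of one protein family are mapped onto structure-based multiple
    alignments and clustered into binding regions by interacting-residue
    overlap, producing a family/binding-region/interface hierarchy; observed
    regions are transferred across structurally similar families through
    non-sequential alignment correspondence maps to yield predicted binding
    regions. Includes a deterministic synthetic-fixture generator for
    end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
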