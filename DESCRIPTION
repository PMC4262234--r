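Package: dsloop
Title: Survey of Short Disulphide-Bonded Protein Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects short disulphide-bonded loops (two bond-forming cysteines
    enclosing a handful of interior residues) in three-dimensional protein
    complexes and classifies them by surface exposure, protein-protein
    interface membership and interface coverage; scores the evolutionary
    conservation of loop interiors against their immediately flanking
    ("juxtapeptide") residues with Jensen-Shannon divergence column scores;
    and screens viral proteins for loops that mimic human disulphide-bonded
    loops using self-alignment-normalized BLOSUM62 similarity supported by
    shared interactors in merged PSI-MITAB interaction networks. A synthetic
    data module generates seeded toy structures, alignments, structure-state
    predictions and interaction networks with planted signal so that every
    stage of the survey is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    Biostrings,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
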