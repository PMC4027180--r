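Package: wingbind
Title: Quantitative Analyses of a Winged Helix-Turn-Helix DNA-Binding Protein
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for the solution-state characterization of a
    small winged helix-turn-helix transcription factor and its operator DNA.
    Implements operator-motif discovery (TTAA-N7-TTAA paired sites with
    transcription-start-site coordinate arithmetic), secondary-structure
    calling from backbone chemical shifts (chemical shift index), DNA-binding
    interface mapping by chemical shift perturbation, rotational correlation
    time and hydrodynamic radius from 15N relaxation via the
    Stokes-Einstein-Debye relation, sequential two-site ITC binding model
    simulation and fitting, titration breakpoint / melting / Hill
    cooperativity analyses, and NMR ensemble coordinate quality statistics.
    A deterministic synthetic-data generator emulates every input type so
    the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
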