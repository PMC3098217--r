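Package: betatopo
Title: Beta-Sheet Topology Classification and Replica-Exchange
    Thermodynamics for Amyloid Oligomers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing early amyloid oligomers from
    coarse-grained replica-exchange simulations of short peptides such as
    GNNQQNY. Detects backbone hydrogen bonds with the DSSP electrostatic
    criterion, clusters peptide chains into beta-sheets by strand
    attachment, and reports configuration types together with strand
    orientation, register and sheet-character statistics. Includes
    replica-exchange analysis utilities (Metropolis exchange probability,
    binless temperature-WHAM reweighting, specific-heat curves and melting
    temperatures, convergence checks, replica demultiplexing, nucleation
    detection) and generators for idealized beta-sheet assemblies,
    random-coil starting configurations and two-state replica-exchange
    energy traces used as controlled fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
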