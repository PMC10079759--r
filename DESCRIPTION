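Package: ploidynet
Title: Realizing Ploidy Profiles as Phylogenetic Networks with Beads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constructs rooted phylogenetic networks (allowing beads, i.e.
    pairs of parallel arcs modelling whole-genome duplication) that realize a
    ploidy profile: a vector recording, for each taxon, its ploidy level as
    the number of root-to-leaf paths in the network. Implements the
    simplification sequence of a profile, core networks driven by the binary
    representation of an integer, the traceback construction N(m), (weak)
    HGT-consistent time-stamp labellings and horizontal arcs,
    cherry-modification (orchard) analysis, tree-based and tree-child tests,
    and split/unzip operations on ploidy-profile space, together with
    extended-Newick, JSON and DOT input/output and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
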