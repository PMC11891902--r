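Package: hacg
Title: Martini 3 Coarse-Grained Modelling Toolkit for Hyaluronic Acid
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds, validates and analyses Martini 3 coarse-grained models
    of hyaluronic acid (HA) and its monosaccharides. Generates GROMACS-ready
    topologies (ITP/TOP/GRO/MDP) for HA chains of arbitrary length from the
    disaccharide parameter tables via the chain periodicity rule, maps
    atomistic structures onto coarse-grained beads by center of geometry,
    evaluates the bonded energy terms (harmonic bonds, G96 cosine and
    restricted bending angles, harmonic impropers, proper dihedrals), and
    computes chain observables: bond-vector autocorrelation and worm-like
    chain persistence length, radius of gyration, end-to-end distance,
    solvent-accessible surface area with bead-class radii, and aggregate
    clustering. Includes synthetic generators (worm-like chain ensembles,
    perturbed geometries, toy atomistic fragments) for testing.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
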