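Package: avm
Title: Active Vertex Model Simulation of Confluent Epithelial Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cell-resolution simulation of confluent epithelial tissue mechanics
    using an active vertex model. Cell centres move under forces derived from the
    vertex-model energy evaluated on the dual Voronoi tessellation of a Delaunay
    triangulation that is maintained by equiangulation edge flips (the natural
    realisation of T1 neighbour exchanges), with active self-propulsion along a
    fluctuating polarity, three polarity-alignment models, cell growth, division
    and death, and a flexible ghost-particle boundary line with line tension and
    bending stiffness. Includes scenario generators (disk, annulus, rectangular
    strips, confined cavity), trajectory observables (self-intermediate scattering
    function and alpha-relaxation time, T1 statistics, virial/Hardy stress and
    pressure, neighbour-number distributions, demixing index) and phase
    classification of solid-like, liquid-like and boundary-unstable states.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
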