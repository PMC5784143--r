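Package: PlanarOrder
Title: Quantifying Translational, Entropic and Angular Order in Planar
    Dispersions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the spatial order of two-dimensional
    dispersions of objects (nanoparticles, micelles, cells) from their
    centroid coordinates. Implements pair correlation functions with
    bootstrap smoothing for small samples, window-clipped Voronoi
    tessellation metrics (coordination numbers, local hexagonal radii,
    a lattice disorder parameter), facet-weighted Minkowski bond
    orientational order parameters for arbitrary symmetry bases, and
    entropic valence (first-neighbour probability) maps. Includes
    generators for reference patterns: hexagonal and square lattices,
    Gaussian-jittered hexatic ensembles, complete spatial randomness,
    and a confined-packing fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    deldir,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'bond-order.R'
    'pair-correlation.R'
    'point-io.R'
    'report.R'
    'show-methods.R'
    'synthetic.R'
    'valence.R'
    'voronoi.R'
    'zzz.R'
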