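Package: poretrace
Title: Geometric Detection and Characterization of Channels in Molecular
    Structures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Parameter-free identification of channels, pockets and internal
    voids in atomic structures represented as collections of spheres. Builds
    the weighted Delaunay (regular) triangulation of probe-inflated atoms,
    classifies the alpha complex at alpha = 0, segments the complement by a
    discrete-flow procedure from infinity, and selects the channel as the
    largest cavity with at least two mouths. The channel is then characterized
    geometrically: a skeleton graph is pruned to the core path maximizing a
    length-squared over tortuousness score, a clearance-weighted centerline
    with Frenet frames yields curvature, torsion and a pore radius profile,
    and planar cross-sections orthogonal to the centerline are reduced to
    their visible contour and summarized by closest/farthest distances and a
    best-fit ellipse. A trajectory mode analyzes molecular dynamics frame
    series with warm starts, and a synthetic fixture generator produces toy
    molecules (cylindrical pores, torus channels, pockets, sealed voids,
    helical and pentalobed tubes) with analytically known geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
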