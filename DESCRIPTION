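Package: neuroprint
Title: 3D-Printable Surface Meshes from Traced Neuronal Morphologies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts traced neuronal reconstructions (SWC and a restricted
    Neurolucida ASC dialect) into watertight, optionally colored,
    3D-printable triangle meshes. Provides morphology repair (reattachment
    of detached dendrites to the soma centroid), diameter adjustment
    policies, soma rescaling about its center of mass, watertight surface
    tessellation of the frustum union via a signed-distance field and
    marching tetrahedra (robust to interpenetrating neurites), mapping of
    surface triangles back to the underlying neurite segments for coloring,
    printability validation against minimum wall-thickness rules, STL and
    VRML97 export with printed-volume and bounding-box metadata, and a
    synthetic-morphology generator for testing every stage without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, Rcpp, igraph, jsonlite, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
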