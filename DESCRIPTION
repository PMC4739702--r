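Package: dentaltopo
Title: Dental Topographic Analysis of Triangulated Surface Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the shape of 3D triangulated polygon surfaces with
    three complementary dental topographic metrics: Dirichlet normal energy
    (surface bending), relief index (surface relief), and orientation patch
    count rotated (surface complexity, computed directly from polygon meshes
    rather than raster elevation grids). Includes ASCII and binary Stanford
    PLY input, OFF export, rigid mesh transforms, implicit-fairing smoothing,
    a batch driver with tab-separated output, deterministic synthetic mesh
    generators with known analytic area, curvature and patch structure for
    verification, and the statistical comparison layer (one-way ANOVA, Tukey
    HSD, ordinary least squares) used to validate mesh-based complexity
    against legacy elevation-grid complexity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
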