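Package: voxelskel
Title: Topology-Preserving Voxel Skeletons of Living Plant Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts curve skeletons from 3D point clouds of anastomotic
    plant structures (living root bridges, inosculated 'Baubotanik' joints).
    The pipeline voxelises a cloud on an octree-style lattice, removes noise,
    fills surface holes and internal space, and thins the solid with a
    sequential, directional, template-driven algorithm whose deletion tests
    are adjusted P-simplicity criteria, so that connected components, loops
    (anastomoses) and cavities are preserved exactly.  Per-voxel iterations
    of exposure are recorded during thinning and drive a volume
    reconstruction with circular or elliptical cross-sections, including a
    linear model that predicts the elliptical ratio of a section from
    exposure-iteration ratios.  Synthetic tubular phantoms (cylinders,
    elliptical tubes, tori, Y-junctions) with known centerlines, radii and
    Betti numbers make every stage testable, and assessment helpers cover
    homotopy, thinness, centeredness, volume reconstructibility, noise
    robustness and rotational invariance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
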