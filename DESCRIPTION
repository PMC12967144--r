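Package: vemmorph
Title: Morphometry, Karyotyping and Spatial Statistics for Volume Electron Microscopy Label Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of segmented serial block-face scanning
    electron microscopy (SBF-SEM) volumes of dividing cells. Computes per-object
    3D morphometry (voxel-count volume, iso-surface mesh area, centre of mass,
    integrated stain density) from integer label volumes with nanometre voxel
    metadata, reconstructs ultrastructure-based karyotypes of metaphase
    chromatids (centromere classification from geodesic width profiles, homolog
    pairing, sex-chromosome identification, volume-ordered karyotype tables),
    derives chromosomal and organelle spatial statistics (distance matrices,
    mutual k-nearest-neighbour networks, silhouette-selected K-means and
    BIC-selected Gaussian mixture clustering), builds major-axis-aligned,
    voxel-corrected 3x3 regional organelle density maps and kernel density
    hotspot maps, and compares mitotic phases with Welch t-tests. A synthetic
    phantom generator produces label and intensity volumes with known ground
    truth so that every stage of the pipeline can be validated without original
    image stacks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    cluster,
    mclust,
    MASS,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
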