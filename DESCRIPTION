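Package: filnet
Title: Graph Reconstruction and Quantification of Keratin Filament Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms active-contour ("snake") segmentations of 3D
    fluorescence image stacks of keratin intermediate-filament networks into a
    coherent node/segment graph and quantifies network architecture per cell:
    bundling (brightness), segment length, filament density, branching degree,
    bending, curvature, apparent persistence length, orientation isotropy and
    estimated keratin protein mass.  Includes a rendering-based validation of
    the segmentation against the original image stack and a synthetic-data
    generator producing ground-truth networks, snake files and noisy voxel
    stacks so the whole pipeline is testable without microscopy data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    tiff,
    jsonlite,
    yaml,
    igraph,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
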