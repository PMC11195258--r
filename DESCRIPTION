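Package: bootseg
Title: Bootstrapping Dense 3D Instance Segmentation from Sparse 2D Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for generating dense 3D instance segmentations of volumetric
    microscopy (e.g. serial-section electron microscopy of brain neuropil) from
    sparse 2D annotations. A 2D network is trained on sparsely annotated
    sections with a masked weighted mean-squared-error loss to predict dense
    local shape descriptors; a lightweight 3D network, pre-trained purely on
    synthetic instance labels generated on the fly, turns stacked 2D
    descriptors into direct-neighbor 3D affinities; watershed supervoxels and
    hierarchical agglomeration on a region adjacency graph produce instance
    segmentations; the result can be used unproofread as pseudo ground truth
    to bootstrap a 3D multi-task (affinities + descriptors) model. Includes
    skeleton-based split/merge edit counting (an adapted min-cut metric),
    variation of information, descriptor error maps, and volume/skeleton I/O
    (Zarr, N5, TIFF, SWC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    tiff,
    withr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
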