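Package: declutter
Title: Calcium Imaging Trace Analysis with Functional PCA Denoising and Clustering
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of single-channel fluorescence time-lapse
    recordings of intracellular calcium: rigid drift correction by subpixel
    phase correlation, semi-automated soma segmentation (seeded tessellation
    combined with Li minimum cross-entropy thresholding), per-ROI mean-gray
    trace extraction, baseline (dF/F0) normalization, dense-grid functional
    principal component analysis for denoising and dimension reduction,
    k-means clustering of component scores with elbow-based model selection,
    and UMAP embedding for display. Includes a ground-truthed simulator of
    stimulus-locked calcium transients (traces and full movies) so that every
    stage can be validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    uwot,
    yaml,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    optparse,
    withr
Config/testthat/edition: 3
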