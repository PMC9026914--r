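Package: mitoscreen
Title: Mitochondrial Health Assays from High-Content Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies mitochondrial health from multi-channel high-content
    fluorescence images of well plates: mitochondrial hydrogen peroxide as the
    colocalized-area fraction of enhanced MitoPY1-like speckles with a
    mitochondrial mask, membrane potential as the JC-10 orange/green
    aggregate-to-monomer intensity ratio under mutual masking, and morphology
    as a grayscale granular spectrum (fragmentation) plus skeleton endpoint
    geodesic lengths. Includes Operetta-style filename parsing, polynomial
    illumination correction, Otsu two- and three-class and minimum
    cross-entropy thresholding, propagation-based cell segmentation, a
    synthetic plate generator with ground truth for validation, and
    well/condition-level statistics (ANOVA with Tukey post-hoc, t-tests,
    boxplot-rule outlier flagging).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    igraph,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
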