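Package: cribnet
Title: Cribriform Growth Pattern Detection in Prostate Biopsy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of the cribriform Gleason grade 4 growth pattern in
    hematoxylin-and-eosin stained prostate needle biopsies with a coarse-output
    multi-class segmentation convolutional neural network. Provides optical-density
    background masking, overlapping patch tiling with centre-crop reassembly,
    a squeeze-and-excitation residual network trained with a class-weighted soft
    Dice loss, checkpoint selection by a Dice/specificity validation metric,
    ensemble averaging, region-based ROC and FROC evaluation with a minimum-area
    filter, ASAP-style XML polygon annotation input and output, and a procedural
    generator of synthetic biopsy images with pixel-accurate reference masks so
    that the whole pipeline can be trained and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    xml2,
    jsonlite,
    yaml,
    png,
    digest
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff,
    withr,
    EBImage
Config/testthat/edition: 3
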