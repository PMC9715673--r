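Package: saliret
Title: Saliency-Guided Content-Based Medical Image Retrieval
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for disease-targeted content-based image retrieval on
    grayscale radiographs. Implements a small dense-block convolutional
    classifier trained with weighted binary cross-entropy, Deep Taylor
    relevance propagation for saliency maps, an interpretability-guided
    retrieval pipeline in which the classifier is retrained on its own
    saliency maps, a dual-attention comparator with self-attention and
    multi-level attention fusion, SSIM and feature-distance retrieval
    baselines, and ranking evaluation with the normalised discounted
    cumulative gain. Ships a synthetic phantom radiograph generator with
    known disease-severity ground truth so the full retrieval benchmark runs
    end-to-end on commodity CPUs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
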