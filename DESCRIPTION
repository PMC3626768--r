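Package: rfacover
Title: Quantitative Assessment of Radiofrequency Ablation Coverage on Liver CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how completely a radiofrequency ablation (RFA)
    covered a hepatic tumor, by comparing the tumor segmented on pre-treatment
    CT with the coagulation necrosis segmented on post-treatment CT. Provides
    semi-automatic fuzzy c-means segmentation of tumors and necroses driven by
    operator seed pixels, non-rigid realignment of the post-treatment volume
    (global affine plus B-spline free-form deformation maximising normalised
    mutual information, with synthetic-pattern replacement of both lesions so
    that their intensity difference cannot drive the registration), four
    slice-wise coverage indexes (residual tumor, tumor-free margin,
    inter-barycentric distance, orientation index), a segmentation validation
    metric suite, and a synthetic CT phantom generator with known geometry,
    noise and deformation for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    optparse,
    png,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
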