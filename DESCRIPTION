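Package: shoalSE
Title: Shannon Entropy of Shoaling-Fish Centroid Trajectories and an
    Entropy-Based Biological Warning System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the collective behavior of shoaling fish from
    overhead video: simulation of seeded synthetic shoals (cohesive,
    intermittent correlated random walks in a 640x480-pixel arena), frame
    segmentation and group-centroid trajectory extraction with K-means
    smoothing, histogram Shannon entropy of basal and post-disturbance clips,
    coefficient-of-variation and power-law (a*n^b + c) characterization of
    entropy versus fish number, and a reference/error-signal alarm model for
    entropy-based biological warning systems in aquaculture monitoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    minpack.lm,
    jsonlite,
    EBImage,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
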