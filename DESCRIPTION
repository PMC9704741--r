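Package: vrmotor
Title: Motor Assessment from Bilateral Virtual-Reality Ball-Catching Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evidence-based upper-limb motor assessment from a
    bilateral virtual-reality ball-catching task used in stroke
    rehabilitation. Segments hand/ball motion-trajectory recordings into
    throw-catch attempts and derives 25 motor indicators (horizontal,
    vertical and full-body: range-entry times, aiming time,
    stabilization-to-catch time, re-entry counts, speed statistics before
    and after the ball's apex, path lengths, movement-ratio and extension
    extents). Clusters clinical scale triples (FMA, TEMPA, WMFT) with
    K-means and silhouette-based model selection into ordered impairment
    levels, tests pre/post efficacy with an exact Wilcoxon signed-rank
    test, correlates indicators with scales and impairment levels
    (Spearman), and trains and cross-validates MLP, RBF-network and SVM
    classifiers that predict impairment level from the indicators,
    reporting accuracy and mean absolute percentage error. Includes a
    physics- and impairment-parameterised session simulator so the whole
    pipeline is reproducible end-to-end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
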