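Package: netconverge
Title: Construction and Convergence of Multimodal Brain Connectivity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds group-level brain connectivity networks from four kinds of
    regional data -- streamline counts from tractography (structural
    connectivity), regional BOLD time series (functional connectivity), and
    across-subject covariance of regional tracer uptake or grey-matter volume
    (covariance networks) -- and quantifies the pairwise similarity of the
    resulting networks in strength (Spearman rank correlation) and in space
    (convergence ratio, a Dice overlap of sparsity-matched binarized networks,
    swept over a sparsity grid and compared against an analytic chance level).
    Includes a synthetic-cohort generator with a planted, spatially embedded
    ground-truth network so the whole pipeline can be exercised and validated
    end to end, plus robustness variants: omitting rank-Gaussian resampling,
    omitting or relaxing the consistency threshold, distance residualization
    with partial rank correlations, positive-weight-only correlations, and
    cortex-only analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
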