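Package: agenoise
Title: Transcriptional Noise and Aging Differential Expression for Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resampling-based quantification of cell-to-cell transcriptional
    noise in aging single-nucleus RNA-seq data, together with the surrounding
    analysis stages: nucleus-level quality control, library-size equalisation
    by exact UMI down-sampling, young/old cell-number balancing, per-cell-type
    old-versus-young Wilcoxon differential expression with shared-gene and hub
    aggregation, expression-bin-matched gene-set module scoring, and
    regulon-based hub transcription-factor ranking. A negative-binomial
    multi-sample, multi-cell-type count simulator with known ground truth
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
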