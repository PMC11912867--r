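Package: grnest
Title: Gene Regulatory Network Assembly and Transcription Factor Activity
    Estimation for Nematode Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds weighted gene regulatory networks for Caenorhabditis
    elegans (and similar compact-promoter organisms) by integrating ChIP-seq
    peaks, in vitro DNA-binding motifs and yeast one-hybrid interactions;
    refines them with high-occupancy-target (HOT) region exclusion and
    cross-species motif-conservation scoring over orthologous promoters;
    estimates transcription-factor activities from differential-expression
    signatures with univariate/multivariate linear models and weighted sums;
    and benchmarks any network against TF-perturbation signatures with
    AUROC/AUPRC and shuffled-network nulls. A synthetic-data module generates
    every input with known ground truth so the full pipeline is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
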