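Package: crnntfbs
Title: Convolutional-Recurrent Prediction of Transcription Factor Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and applies a convolutional-recurrent neural network that
    classifies fixed-length DNA reads as transcription-factor binding or
    non-binding, using dinucleotide-preserving shuffles of the binding reads as
    negatives. Scans ChIP-Seq peak sequences with a sliding window, compares
    neural scores against classical position-weight-matrix log-odds scoring to
    flag non-canonical binding sites, performs in-silico saturation mutagenesis
    of candidate sites, and correlates predicted binding scores with measured
    dissociation constants. A synthetic-data generator with planted motifs,
    decaying peak signal and censored affinity measurements makes every stage
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
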