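Package: kmerscore
Title: Alignment-Free k-mer Sequence Comparison and Score Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An alignment-free sequence-comparison engine based on k-mer
    count and frequency vectors for DNA and protein sequences, together
    with a calibration framework that turns raw similarity scores into
    cut-off thresholds and probabilities of correct prediction. Implements
    the D2 statistic and its cosine-normalised form, Euclidean, Manhattan,
    Chebyshev and normalised Canberra distances on frequency vectors,
    Bray-Curtis dissimilarity and the Normalised Google Distance on count
    vectors, and the Markov-background-corrected d2Star and d2S statistics.
    Supports spaced k-mers via binary masks, a reduced 10-letter amino-acid
    alphabet, all-vs-all and interleaved-pair search with length-ratio and
    cut-off filters, score-frequency histograms, the overlapping index
    between score distributions, cumulative-difference cut-off selection,
    top-hit and ROC/AUC evaluation against external truth tables, and
    deterministic synthetic-data generators (Markov-signature genomes,
    genome fragment extraction, mutated protein ortholog pairs) for
    benchmarking without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
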