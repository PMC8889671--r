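Package: cas13design
Title: CRISPR-Cas13 Guide RNA Knockdown Efficacy Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design and efficacy classification of 28-nt CRISPR-Cas13
    guide RNAs against a reference transcriptome. Enumerates all candidate
    spacers over target transcripts, searches them transcriptome-wide with
    bounded mismatch tolerance, derives positional k-mer, composition,
    target-position, protein-occupancy-overlap and multi-target features,
    selects features by chi-squared enrichment, Kruskal-Wallis, univariate
    regression significance, Z-score thresholding and Gini importance, and
    classifies guides into four knockdown-efficacy quartile classes with a
    decision-tree model. Evaluation follows a noise-normalized
    cross-validation protocol that corrects accuracy for label
    disagreement between experimental replicates sharing identical
    features. Includes a synthetic fixture generator with plantable
    sequence, position and occupancy signals for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    class,
    e1071,
    randomForest,
    rpart,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
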