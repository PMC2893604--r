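Package: pripper
Title: Caspase Cleavage-Site Prediction and In-Silico Proteome Digestion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and applies pattern-recognition classifiers (nu-SVM with
    an RBF kernel, random forest, CART decision tree, and a strict-majority
    Vote ensemble) to predict caspase cleavage sites in protein sequences
    from windowed one-hot amino-acid encodings. Provides leave-one-out and
    bootstrap ROC evaluation protocols, a synthetic training-corpus
    generator with planted caspase motifs, and in-silico digestion of
    arbitrary numbers of proteins into cleavage-product FASTA databases
    for tandem mass-spectrometry searching.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    ranger,
    rpart,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
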