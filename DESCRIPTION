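Package: ncaaprop
Title: AAindex Physicochemical Property Prediction for Non-Canonical Amino Acids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates AAindex physicochemical property scales for
    non-canonical amino acids (ncAAs) from their SMILES strings. For each
    property, a linear model is trained on 13 integer substring-count
    descriptors of the 20 canonical amino acids using F-gated stepwise
    multiple regression; the F threshold is chosen by leave-one-out
    cross-validation and prediction quality is reported as the LOO Pearson
    correlation and RMSE. Includes an AAindex1 flat-file parser, a SMILES
    tokenizer and component counter, an element-domain filter, a
    synthetic-property generator for validation, and writers for a
    predicted-property database over ncAA tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
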