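Package: glycanMLM
Title: Tokenized Graph Transformer Masked-Language Modeling for Glycans
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Represents glycans written in IUPAC-condensed notation as rooted
    labeled trees of monosaccharides and glycosidic linkages, tokenizes them
    as flat node/edge token sequences with seeded orthogonal random feature
    node identifiers, and pretrains a pure-transformer encoder with a masked
    language modeling objective over both token types. Pretrained models
    supply whole-glycan embeddings for downstream classification, rank
    candidate completions for ambiguously annotated structures (hit at K),
    and the package additionally provides a Weisfeiler-Lehman subtree kernel
    for structural similarity analysis, a probabilistic grammar generator for
    synthetic branched glycans, and corpus curation utilities (ambiguity
    filtering and linkage-variant expansion).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
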