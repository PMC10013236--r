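Package: noveltylbd
Title: Literature-Based Discovery from Important Triples
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An A-B-C literature-based discovery (LBD) system over
    subject-predicate-object (SPO) predications between biomedical
    concepts, with a machine-learning front end that restricts discovery
    to "important" (novelty-representing) triples. Includes readers and
    writers for dated, sectioned predication corpora and word2vec-style
    embedding files; a three-way cosine-sum triple similarity used to
    label body triples against abstract triples; two importance
    classifiers (a fully connected network with halving layer widths
    over full-text features, and a masked-element language model over
    triples with a binary classification head); candidate hidden
    knowledge pair (CHKP) extraction by sparse adjacency-matrix
    squaring; timeslicing evaluation against gold standards built to
    avoid rewarding background knowledge; and a seeded synthetic-corpus
    generator with planted importance and hidden-knowledge structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
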