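Package: casecontext
Title: Case-Level Context for Classifying Sequences of Clinical Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Modular add-ons for capturing case-level context when classifying
    sequences of related clinical documents such as cancer pathology reports.
    Baseline per-document encoders (a word-level convolutional network and a
    hierarchical self-attention network) produce document embeddings, and five
    context mechanisms (concatenation, GRU, GRU with linear-chain CRF,
    multi-head self-attention, and self-attention with linear-chain CRF)
    transform them into context-aware per-report predictions, in both
    bidirectional (offline) and unidirectional (online) scenarios. Includes
    the full text-preprocessing procedure, date-based dataset splitting,
    modular and end-to-end training with early stopping, evaluation with
    accuracy and macro F-score, bootstrap confidence intervals, McNemar's
    test, and a synthetic case-corpus generator for controlled experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
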