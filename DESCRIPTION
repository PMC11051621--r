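Package: ddiextract
Title: Drug-Drug Interaction Extraction from Text with Knowledge-Subgraph Enhancement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sentence-level drug-drug interaction (DDI) classification that
    fuses contextual text features with a drug-pair representation learned
    from the pair's enclosing subgraph in a typed biomedical knowledge
    graph. Provides a SemEval-2013 Task 9 corpus parser with candidate-pair
    generation and negative-instance filtering, k-hop enclosing-subgraph
    extraction with double-radius distance labels, an attention-gated
    relational graph network with basis-decomposed relation weights, three
    text/graph feature-fusion heads, a multi-class focal loss with
    count-derived class weights, micro/macro precision-recall-F1/AUC/AUPR
    evaluation, and a synthetic corpus + knowledge-graph generator with
    controllable label signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
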