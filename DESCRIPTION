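Package: piecemeal
Title: Piecemeal Causal Discovery and Experiment Selection from
    Two-Variable Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Synthesizes two-variable study results into equivalence
    classes of causal directed acyclic graphs and plans the next most
    informative experiment.  Interventional (in)dependence statements are
    encoded as weighted constraints; the DAGs minimizing the summed
    weight of unsatisfied constraints form the equivalence class, whose
    remaining underdetermination is quantified as per-pair degrees of
    freedom.  Follow-up experiments are chosen by degrees-of-freedom or
    expectation policies, hypotheses are categorized by whether testing
    them can prune the class, and oracle-driven simulations replay the
    whole protocol over every four-variable causal structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
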