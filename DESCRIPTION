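Package: statemerge
Title: Choosing State Structures in Markov Cost-Effectiveness Models by
    Parameter Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares candidate state structures for discrete-time Markov
    cost-effectiveness models by re-expressing merged-state models as
    split-state models with equality constraints on outward transition
    probabilities, costs and utilities.  Constrained and unconstrained
    multinomial models are fitted by maximum likelihood and compared with
    Akaike's information criterion; implicit event counts can be derived
    from published risk summaries.  A cohort engine verifies the
    merged/constrained-split equivalence and propagates structures to
    decision-analytic outputs: net monetary benefit, cost-effectiveness
    acceptability, and the expected value of (partial) perfect
    information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    mgcv,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
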