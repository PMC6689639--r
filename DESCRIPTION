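Package: labevolve
Title: Evolutionary Dynamics of Research Lab Populations under Funding Policies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of a community of research labs whose
    methodological rigour (intrinsic false positive rate) evolves by
    death-birth selection on publication counts with Gaussian trait
    mutation. Research output is filtered by publication bias against
    negative results and by peer review, and lab productivity is
    constrained by grant funding allocated under five strategies:
    publication history, methodological integrity, random allocation, a
    mixed strategy, and a modified (threshold) lottery. Includes a
    compiled simulation engine, closed-form expectations for a static
    fully funded population used as Monte Carlo ground truth, and
    replicated parameter sweeps with equilibrium summaries of the
    community mean false positive rate and the false discovery rate of
    the published literature.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
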