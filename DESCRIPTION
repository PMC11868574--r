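Package: confactory
Title: Active-Learning Data Factory for Molecular Conformational Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for building labeled datasets of molecular conformational
    energies with an active-learning acquisition loop. Provides strict
    Bemis-Murcko scaffold splitting with a Tanimoto similarity constraint,
    an ensemble of trainable energy predictors with analytic forces,
    candidate ranking by ensemble disagreement (relative standard deviation)
    or by MACCS-fingerprint loss prediction, a Pool/Buffer/Seed data-stream
    simulation harness for comparing selection strategies, Langevin molecular
    dynamics driven by ensemble forces with a gradient-cosine confidence
    score for frame selection, and a file-based task broker with redundant
    result verification for distributing labeling work. A synthetic molecule
    library and an analytic bonded plus Lennard-Jones labeling oracle make
    the whole pipeline runnable at desk scale without quantum chemistry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    parallel,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
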