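Package: commgeom
Title: Geometry of Community Aggregate-Property Responses to Perturbations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents ecosystem functions and diversity metrics as
    directions in community state space and relates their collinearity to
    the probability that they respond in qualitatively opposite ways
    (mismatch) to a perturbation. Provides the geometric core (projection
    responses, collinearity angles, Hill diversity and its gradients,
    function broadness, biomass-scaled angles), an in-silico
    perturbation-experiment simulator, calibration-based estimators of
    function broadness, population-level response diversity and the
    biomass-scaling exponent of perturbations, and a research-synthesis
    pipeline for long-format effect-size tables (log response ratios) from
    perturbation experiments, including a Gram-matrix validation test and
    a Kamada-Kawai function-similarity network. A synthetic effect-size
    generator with ground-truth bookkeeping makes every stage testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
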