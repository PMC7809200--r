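Package: lifespanEF
Title: Lifespan Trajectories of Executive Function from Trial-Level Task Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores four executive-function tasks (Stroop colour-word,
    operation span, alternating-runs task switching, Tower of Hanoi) from
    trial-level records, fits linear/quadratic/cubic orthogonal-polynomial
    age-trajectory models with IQ and socio-economic covariates, selects the
    best-fitting degree by a majority vote over nested-test p-values, AIC and
    BIC, tests whether two measures share a developmental trajectory via a
    z-scored stacked interaction model, and computes raw and age-adjusted
    partial correlations among the measures.  A synthetic-cohort simulator
    reproduces the task designs (pseudo-randomised Stroop sequences,
    quadrant-rotation switching blocks, letter spans, Tower of Hanoi problems
    generated by breadth-first search over the 81-state move graph) so the
    whole pipeline can be exercised and validated without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
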