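Package: limnocw
Title: Cold/Warm Coding of Climate-Sensitive Phases in Dimictic Aquatic Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects four climate-sensitive hydrographic phases (inverse winter
    stratification, spring overturn, early thermal stratification, summer
    stagnation) from depth-resolved water-temperature time series of dimictic
    lakes and coastal seas, transfers phase timing across latitude by matching
    cumulative clear-sky solar radiation, classifies every phase of every year
    as cold or warm against reference-period thresholds, and quantifies
    cross-system coherence (similarity, Phi coefficient, odds ratio, Fisher's
    exact test), long-term warming trends (binomial-logit GLM, Mann-Kendall)
    and phase-conditioned responses (Brunt-Vaisala stability, Levene and
    Mann-Whitney tests). Includes a synthetic dimictic-lake generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    car,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
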