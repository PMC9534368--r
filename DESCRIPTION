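Package: cpmcluster
Title: Phenotyping Conditioned Pain Modulation and Temporal Summation
    Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quantitative-sensory-testing analysis pipeline for
    conditioned pain modulation (CPM) assessments. Scores raw
    psychophysical session time series (thermode ramp pretests, tonic
    heat test stimuli rated on a 0-100 computerized visual analogue
    scale, and a cold-pressor conditioning stimulus rated on a 0-10
    numerical rating scale) into per-participant indicators: heat pain
    threshold, T50, temporal summation of pain (TSP), conditioning
    stimulus mean pain with early-withdrawal imputation, and CPM
    efficiency with optimal/suboptimal/inefficient categories. Patients
    are phenotyped by hierarchical Ward clustering of the four z-scored
    indicators with k-means consolidation, the partition chosen by the
    highest relative loss of within-cluster inertia. Reporting
    statistics include Pearson chi-squared tests, gender-controlled
    one-way ANOVA with omega-squared effect sizes, Scheffe and Fisher
    LSD pairwise comparisons, and Spearman correlations with Fisher-z
    confidence intervals. A synthetic cohort generator emits raw
    session traces from a three-phenotype patient mixture plus controls
    so the whole pipeline can be exercised end to end with a known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
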