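Package: micromed
Title: Mediterranean-Diet Adherence Scoring and Quantitative Microbiome
    Analysis for Paired Intervention Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for microbiota-targeted Mediterranean-diet intervention
    studies. Implements a daily 0-30 Mediterranean-diet adherence score from
    checklist questionnaires, quantitative microbiome profiling (scaling of
    relative abundances by qPCR-derived bacterial loads), construction of
    paired post-minus-pre delta-abundance matrices with retention filters,
    Bray-Curtis dissimilarity, principal coordinates analysis, PERMANOVA with
    subject-identity blocking (restricted permutations), Spearman correlation
    screens with Benjamini-Hochberg false discovery rate control, ordinary
    least-squares covariate models, and a synthetic paired-cohort generator
    with planted diet-microbiome-inflammation effects for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
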