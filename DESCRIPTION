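Package: nciiGCA
Title: Combining Ability, GCA-GWAS and Breeding-Era Trends for NCII Maize Testcross Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for North Carolina design II (line x tester) testcross
    trials in maize breeding. Implements Griffing-style estimation of general
    and specific combining ability (GCA/SCA) from plot totals, balanced
    factorial analysis of variance for per-tester and joint combining-ability
    layouts, multi-environment BLUP of hybrid values via REML, variant-level
    quality control and single-marker association mapping of per-line GCA
    values, and analyses of GCA trends and homozygote allele-class frequency
    trajectories across breeding eras. A seeded synthetic-data generator
    emulates a replicated multi-location testcross trial with era-structured
    causal allele frequencies so that every stage of the pipeline can be
    exercised and validated without access to proprietary trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
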