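Package: straitsadmix
Title: Sex-Biased Admixture Inference from Ancestry Tracts and Uniparental Haplogroups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the admixture history of recently admixed
    human populations such as the Peranakan Chinese of the Malay Archipelago.
    Provides a synthetic-cohort simulator (Balding-Nichols allele frequencies,
    Poisson-process local-ancestry tracts, sex-biased founder lineages with
    mitochondrial and Y haplogroups), reference-space principal component
    analysis with projection, Procrustes similarity and iterative outlier
    removal, tract-based global ancestry fractions with posterior masking, the
    three-population f3 admixture test with block-jackknife standard errors, a
    Bayes estimator of maternal and paternal ancestry contributions from
    uniparental haplogroups with categorical-resampling inference, and
    admixture dating from the exponential decay of ancestry autocovariance
    with genetic distance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
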