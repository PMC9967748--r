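Package: mycoarch
Title: Intratumor Mycobiome and Archaeome Analysis from RNA-Seq Read Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intratumor fungal and archaeal communities
    inferred from non-human RNA-seq read counts. Provides contamination
    correction by three deterministic batch-effect detectors (sequencing-date
    clustering, sequencing-plate disproportion, and total-abundance slope),
    centered log-ratio (Aitchison) transformation, Kruskal-Wallis differential
    abundance with Bonferroni correction and log-fold-change calls across
    tumor/normal, histologic-subtype, gender, and mutation-status cohorts,
    direction-concordant Venn partitioning of shared hits, clinical-variable
    association, and continuous-phenotype gene-set enrichment with a weighted
    Kolmogorov-Smirnov running-sum statistic and phenotype permutation. A
    synthetic-data generator with a planted ground-truth manifest makes the
    whole pipeline testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
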