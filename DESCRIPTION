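Package: ceRNAprog
Title: Competing-Endogenous-RNA Network Discovery and Prognosis from
    Tumor/Normal Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for identifying lncRNA-miRNA-mRNA
    competing-endogenous-RNA (ceRNA) interactions from tumor versus normal
    expression cohorts and evaluating their prognostic value. Differential
    expression is called per RNA class with a log-CPM transform and an
    empirical-Bayes moderated t-test; candidate lncRNA-mRNA pairs are scored
    by a hypergeometric shared-miRNA test, Pearson co-expression, and a
    regulation-similarity score over the shared miRNAs; passing pairs are
    assembled into a bipartite-by-miRNA network from which degree-ranked hub
    RNAs and lncRNA-miRNA-mRNA triplets are extracted; triplets are assessed
    by a multivariate Cox risk score with median split, Kaplan-Meier curves
    and log-rank tests. A negative-binomial synthetic-cohort generator with
    planted differential expression, planted ceRNA triplets and
    expression-driven survival provides ground truth for validation, and a
    generic hypergeometric over-representation test covers gene-set
    enrichment of the differential lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    igraph,
    jsonlite,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
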