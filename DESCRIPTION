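Package: archevo
Title: Domain-Architecture Census and Parsimony Analysis of Transcription-Factor Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative-genomic analysis of multi-domain
    transcription-factor families such as the LuxR-type regulators. Builds a
    per-species domain-architecture census from tabular conserved-domain hit
    files using a dual-filter retention rule, infers architecture
    gain/loss/transfer histories on species trees by Dollo-style parsimony and
    explicit origin-hypothesis scoring, censuses monophyletic architecture
    clusters on annotated gene trees, runs an ecological correlation battery
    (Spearman rank correlation with exact small-sample permutation p-values,
    the Eta correlation ratio, Fisher-z power, multiple regression), and
    performs Fisher-exact term enrichment with Benjamini-Hochberg FDR control
    and a most-specific-term filter over an ontology DAG. A fully synthetic
    data generator simulates species trees, architecture evolution with
    fusion, fission, loss, duplication and horizontal-transfer events,
    ecological covariates and annotation sets so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
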