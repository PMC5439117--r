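Package: gcnaclass
Title: Copy-Number-Based Molecular Classification and Survival Analysis of
    Diffuse Gliomas
Version: 0.1.0
Authors@R: person("gcnaclass", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Rule-based molecular re-classification of adult diffuse gliomas
    from copy-number and mutation profiles. Calls discrete copy-number events
    from GISTIC-style gene scores or GRCh37 segment tables (1p/19q codeletion,
    whole-chromosome gains and losses, focal amplifications and homozygous
    deletions), embeds molecular alteration matrices by classical
    multidimensional scaling, assigns the three 2016-WHO molecular clusters
    from IDH1/2 mutation and 1p/19q codeletion status, derives prognostic
    copy-number subtypes (W1-W4 for IDH-wildtype and M1-M3 for IDH-mutant
    astrocytic gliomas), performs Kaplan-Meier and Cox proportional-hazards
    survival analysis, and validates subtype survival across cohorts via
    baseline-normalized median overall survival. Includes a synthetic-cohort
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
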