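Package: pairomics
Title: Integration of Paired Tumor/Normal Expression, Methylation and Copy Number Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how much of the aberrant expression of a gene panel is
    attributable to DNA methylation versus somatic copy number aberration in
    paired tumor/normal designs. Provides per-feature paired t-testing with
    Bonferroni or Benjamini-Hochberg multiplicity control, probe-to-gene
    collapse of significant methylation probes with direction-split handling,
    adjacent-probe copy number calling on log R ratios, Spearman-backed
    starburst classification of differentially expressed genes, cohort-level
    explained-fraction reports, and a synthetic paired-omics generator with
    planted gene classes so every pipeline stage is verifiable by parameter
    recovery.
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
    withr,
    yaml
Config/testthat/edition: 3
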