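# pairomics

Integrative analysis of paired tumor/normal expression, DNA methylation and
copy number profiles.

## The problem

In paired tumor/normal designs (each tumor matched to non-tumor tissue from
the same patient), a gene panel — for example an inflammation-related panel —
shows widespread aberrant expression. How much of that aberrant expression is
attributable to aberrant DNA methylation, how much to somatic copy number
aberration (SCNA), and how much to neither? `pairomics` implements the full
chain from normalized array matrices to a cohort-level answer, for analysts
working with three platform matrices per cohort:

* log2 expression per transcript,
* a normalized methylation score per methylation probe,
* a log R ratio (LRR) per SNP/CN probe,

plus a BED-like annotation mapping every feature to a gene and genomic
position.

## The method

For each feature the within-pair differences `d_i = tumor_i − normal_i` are
tested with a one-sample Student t-test, `t = d̄ / (s_d / √n)`, two-sided on
`n − 1` df. Multiplicity is controlled per platform over the `m` features
actually tested: Bonferroni (`p < α/m`, the default, so e.g. α = 0.05 over
1,108 / 38,179 / 33,855 features gives 4.5×10⁻⁵ / 1.3×10⁻⁶ / 1.48×10⁻⁶) or
Benjamini–Hochberg step-up at FDR α.

Significant probes are then lifted to gene level:

* **Methylation** — the mean of the significant probes' `d̄` per gene; probes
  of opposite direction at one locus are kept as two separate records, each
  carried forward independently.
* **SCNA** — the adjacent-probe spanning rule: only runs of ≥ 2 consecutive
  (by genomic order within the gene) significant same-sign SNP/CN probes
  count; same-direction runs of a gene merge into one per-direction call
  whose mean LRR difference averages over all contributing probes.

Each differentially expressed gene is classified starburst-style per
platform: *explained* requires coordinate direction (hypermethylated & down,
hypomethylated & up; gain & up, loss & down) **and** a significant
sign-consistent Spearman correlation (ρ < 0 for methylation, ρ > 0 for copy
number) between the gene's expression and its gene-level methylation/LRR
values across all 2n samples. The cohort report gives
`frac_meth = n_meth_explained / n_DE`, `frac_cn`, and the union fraction.

A synthetic-data generator plants gene classes (`null`, `expr_only`,
`meth_driven`, `cn_driven`, `dual`) with recorded truth so every stage is
verifiable by parameter recovery.

## Worked example

```r
library(pairomics)

sim <- simulation_config(n_pairs = 30, n_genes = 60, seed = 7)
ds  <- generate_dataset(sim)
res <- run_pipeline(ds$expression, ds$methylation, ds$cnv,
                    ds$annotation, analysis_config())
res$report
#> contribution_report: 30 DE genes
#>   methylation: 6 overlap, 6 explained (frac 0.2000)
#>   SCNA:        7 overlap, 7 explained (frac 0.2333)
#>   both explained: 1; union fraction 0.4000

truth_explained_fractions(ds$truth)[c("meth", "cn", "union")]
#> $meth 0.2   $cn 0.2333   $union 0.4
```

The pipeline found 30 DE transcripts (Bonferroni threshold 0.05/60 =
8.3×10⁻⁴), and its explained fractions match the planted truth exactly on
this seed: 20% of the aberrant expression attributable to methylation,
23.3% to SCNA, 40% to either. The significant transcripts separate tumor
from normal samples almost perfectly
(`cluster_separation(...)` adjusted Rand index 0.933), and each explained
record carries its classification evidence:

```r
res$records[19, c("gene_symbol", "expr_direction", "meth_direction",
                  "rho_meth", "p_meth", "category_meth")]
#>   gene_symbol expr_direction meth_direction  rho_meth       p_meth        category_meth
#> 19   GENE0049           down             up -0.488025 7.640055e-05 explained_hyper_down
```

## Acceptance script

`scripts/acceptance.R` regenerates a seeded 30-pair, 300-gene cohort,
runs the complete pipeline against the installed package, prints the
estimated and planted contribution fractions, and writes its JSON summary:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

* `R/` — matrices/annotation/config IO, differential testing, gene-level
  collapse and SCNA calling, integration, simulator, pipeline.
* `tests/testthat/` — unit, property and end-to-end recovery tests with
  independent oracles.
* `vignettes/integration-methods.Rmd` — model, assumptions, parameter
  choices, limitations.
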