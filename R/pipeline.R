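#' Run the full integration pipeline
#'
#' Chains every stage on the three platform matrices: per-platform paired
#' differential screens (multiplicity controlled within each platform over
#' its tested features), probe-to-gene methylation collapse, adjacent-probe
#' SCNA calling, starburst classification, and the cohort contribution
#' report.
#'
#' @param expression,methylation,cnv [paired_omics_matrix()] objects.
#' @param ann a [probe_annotation()] covering all three platforms.
#' @param config an [analysis_config()].
#' @return a list with `diff_expression`, `diff_methylation`, `diff_cnv`
#'   (per-platform [run_differential()] results), `meth_aggregates`,
#'   `scna_calls`, `records` ([classify_genes()] output), and `report`
#'   (the [contribution_report()]).
#' @export
run_pipeline <- function(expression, methylation, cnv, ann,
                         config = analysis_config()) {
  diff_expr <- run_differential(expression, config)
  diff_meth <- run_differential(methylation, config)
  diff_cnv <- run_differential(cnv, config)
  meth_agg <- collapse_methylation(diff_meth, ann)
  scna <- call_scna(diff_cnv, ann, config$min_adjacent_probes)
  matrices <- list(expression = expression, methylation = methylation,
                   cnv = cnv)
  records <- classify_genes(diff_expr, meth_agg, scna, matrices, ann,
                            config)
  list(diff_expression = diff_expr, diff_methylation = diff_meth,
       diff_cnv = diff_cnv, meth_aggregates = meth_agg,
       scna_calls = scna, records = records,
       report = contribution(records))
}
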