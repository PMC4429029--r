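#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline. Defaults mirror the
#' standard paired-array workflow: family-wise error rate 0.05 controlled
#' by Bonferroni over the features actually tested per platform,
#' uncorrected two-sided Spearman at 0.05 for the expression-coupling step,
#' and SCNA calls requiring at least 2 adjacent significant SNP/CN probes.
#'
#' @param alpha_fwer significance level for the per-platform differential
#'   screen, in (0, 1).
#' @param correction `"bonferroni"` (FWER) or `"bh"` (Benjamini-Hochberg
#'   FDR) multiplicity control.
#' @param spearman_alpha two-sided level for the expression vs
#'   methylation / copy-number Spearman test, in (0, 1).
#' @param min_adjacent_probes minimum run length of adjacent significant
#'   same-sign SNP/CN probes for an SCNA call; at least 2.
#' @param cluster_linkage agglomeration method for the tumor/normal
#'   separation check (any method [stats::hclust()] accepts).
#' @param correlation_samples `"pooled"` correlates across tumor and normal
#'   samples of every pair (2n values); `"tumor"` restricts to tumor
#'   samples.
#' @param seed integer seed for any randomized step.
#' @param output_dir directory for serialized outputs.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(alpha_fwer = 0.05,
                            correction = c("bonferroni", "bh"),
                            spearman_alpha = 0.05,
                            min_adjacent_probes = 2L,
                            cluster_linkage = "average",
                            correlation_samples = c("pooled", "tumor"),
                            seed = 1L,
                            output_dir = ".") {
  correction <- match.arg(correction)
  correlation_samples <- match.arg(correlation_samples)
  stopifnot(
    is.numeric(alpha_fwer), length(alpha_fwer) == 1,
    alpha_fwer > 0, alpha_fwer < 1,
    is.numeric(spearman_alpha), spearman_alpha > 0, spearman_alpha < 1,
    is.numeric(min_adjacent_probes), min_adjacent_probes >= 2
  )
  structure(
    list(alpha_fwer = alpha_fwer, correction = correction,
         spearman_alpha = spearman_alpha,
         min_adjacent_probes = as.integer(min_adjacent_probes),
         cluster_linkage = cluster_linkage,
         correlation_samples = correlation_samples,
         seed = as.integer(seed), output_dir = output_dir),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from JSON or YAML
#'
#' Keys mirror the [analysis_config()] arguments; absent keys take the
#' defaults. YAML requires the optional `yaml` package.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return an [analysis_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(analysis_config, vals)
}
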