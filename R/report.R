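#' Cohort-level contribution report
#'
#' Summarizes, over the differentially expressed (DE) genes of a cohort,
#' how many overlap an aberrant-methylation or SCNA call and how many are
#' *explained* (coordinate direction plus significant sign-consistent
#' Spearman correlation). Fractions are computed from the counts:
#' `frac_meth = n_meth_explained / n_de_genes`,
#' `frac_cn = n_cn_explained / n_de_genes`, and
#' `frac_union = (n_meth_explained + n_cn_explained - n_both_explained) /
#' n_de_genes`.
#'
#' @param n_de_genes number of DE genes.
#' @param n_meth_overlap,n_cn_overlap DE genes that also carry a
#'   gene-level methylation / SCNA call.
#' @param n_meth_explained,n_cn_explained DE genes explained by
#'   methylation / SCNA.
#' @param n_both_explained DE genes explained by both platforms.
#' @return a list of class `contribution_report`; when `n_de_genes` is 0
#'   the fractions are 0 and `zero_denominator` is `TRUE`.
#' @export
contribution_report <- function(n_de_genes, n_meth_overlap, n_meth_explained,
                                n_cn_overlap, n_cn_explained,
                                n_both_explained) {
  counts <- c(n_de_genes, n_meth_overlap, n_meth_explained,
              n_cn_overlap, n_cn_explained, n_both_explained)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (n_meth_explained > n_meth_overlap || n_cn_explained > n_cn_overlap) {
    stop("explained counts cannot exceed overlap counts")
  }
  if (n_both_explained > min(n_meth_explained, n_cn_explained)) {
    stop("n_both_explained cannot exceed either platform's explained count")
  }
  zero <- n_de_genes == 0
  den <- if (zero) 1 else n_de_genes
  structure(
    list(n_de_genes = as.integer(n_de_genes),
         n_meth_overlap = as.integer(n_meth_overlap),
         n_meth_explained = as.integer(n_meth_explained),
         n_cn_overlap = as.integer(n_cn_overlap),
         n_cn_explained = as.integer(n_cn_explained),
         n_both_explained = as.integer(n_both_explained),
         frac_meth = n_meth_explained / den,
         frac_cn = n_cn_explained / den,
         frac_union = (n_meth_explained + n_cn_explained - n_both_explained) / den,
         zero_denominator = zero),
    class = "contribution_report"
  )
}

#' @export
print.contribution_report <- function(x, ...) {
  cat("contribution_report:", x$n_de_genes, "DE genes\n")
  cat(sprintf("  methylation: %d overlap, %d explained (frac %.4f)\n",
              x$n_meth_overlap, x$n_meth_explained, x$frac_meth))
  cat(sprintf("  SCNA:        %d overlap, %d explained (frac %.4f)\n",
              x$n_cn_overlap, x$n_cn_explained, x$frac_cn))
  cat(sprintf("  both explained: %d; union fraction %.4f\n",
              x$n_both_explained, x$frac_union))
  invisible(x)
}

#' Serialize a contribution report to JSON
#'
#' Flat key/value JSON document. Counts are written as integers and
#' fractions with six decimal digits; [read_report()] inverts the
#' serialization.
#'
#' @param report a [contribution_report()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "contribution_report"))
  count_keys <- c("n_de_genes", "n_meth_overlap", "n_meth_explained",
                  "n_cn_overlap", "n_cn_explained", "n_both_explained")
  frac_keys <- c("frac_meth", "frac_cn", "frac_union")
  lines <- c(
    sprintf("  \"%s\": %d,", count_keys, unlist(report[count_keys])),
    sprintf("  \"%s\": %.6f,", frac_keys, unlist(report[frac_keys])),
    sprintf("  \"zero_denominator\": %s",
            if (report$zero_denominator) "true" else "false")
  )
  writeLines(c("{", lines, "}"), path)
  invisible(path)
}

#' Read a contribution report written by [write_report()]
#'
#' @param path path to the JSON report.
#' @return a [contribution_report()].
#' @export
read_report <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep <- contribution_report(
    n_de_genes = vals$n_de_genes,
    n_meth_overlap = vals$n_meth_overlap,
    n_meth_explained = vals$n_meth_explained,
    n_cn_overlap = vals$n_cn_overlap,
    n_cn_explained = vals$n_cn_explained,
    n_both_explained = vals$n_both_explained
  )
  for (k in c("frac_meth", "frac_cn", "frac_union")) {
    if (abs(rep[[k]] - vals[[k]]) > 5e-7) {
      stop("report fractions inconsistent with counts in ", path)
    }
  }
  rep
}
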