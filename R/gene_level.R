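#' Enumerate maximal significant same-sign runs
#'
#' Kernel of the SCNA caller: scans a vector of significance flags and
#' effect signs left to right and returns every maximal run of consecutive
#' positions that are flagged significant and share one sign. Length-1
#' runs are returned; callers filter by minimum length.
#'
#' @param flags logical vector.
#' @param signs numeric vector of the same length; only `sign(signs)` is
#'   used. A flagged position with sign 0 cannot extend or start a run
#'   (a zero within-pair mean difference can never be significant).
#' @return a `data.frame` with columns `start` (1-based), `length`,
#'   `sign` (+1 or -1), in left-to-right order.
#' @export
enumerate_runs <- function(flags, signs) {
  if (length(flags) != length(signs)) stop("length mismatch")
  flags <- as.logical(flags) & sign(signs) != 0
  s <- sign(signs)
  starts <- integer(0); lens <- integer(0); rsign <- numeric(0)
  i <- 1L
  n <- length(flags)
  while (i <= n) {
    if (isTRUE(flags[i])) {
      j <- i
      while (j < n && isTRUE(flags[j + 1L]) && s[j + 1L] == s[i]) j <- j + 1L
      starts <- c(starts, i); lens <- c(lens, j - i + 1L)
      rsign <- c(rsign, s[i])
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(start = starts, length = lens, sign = rsign)
}

# Join differential records with annotation rows of one platform.
# Returns the merged frame (one row per significant probe-gene link) and
# warns about significant probes with no annotation.
join_significant <- function(diff, ann, platform) {
  stopifnot(inherits(diff, "differential_records"),
            inherits(ann, "probe_annotation"))
  ann <- ann[ann$platform == platform, , drop = FALSE]
  sig <- diff[diff$significant, , drop = FALSE]
  unmapped <- setdiff(sig$feature_id, ann$probe_id)
  if (length(unmapped)) {
    warning("unmapped significant probe(s) excluded: ",
            paste(unmapped, collapse = ", "))
  }
  merged <- merge(sig, ann, by.x = "feature_id", by.y = "probe_id",
                  sort = FALSE)
  list(merged = merged, unmapped = unmapped)
}

#' Collapse significant methylation probes to gene level
#'
#' Per gene, the significant methylation probes are grouped by the
#' direction of their tumor-minus-normal change and each non-empty
#' direction group becomes one gene-level record whose `mean_delta` is the
#' arithmetic mean of the group's per-probe mean differences. Genes whose
#' significant probes all agree in direction therefore yield exactly one
#' record; a gene with probes in both directions yields two records
#' (`split_index` 0 for the hypermethylated group, 1 for the
#' hypomethylated one) that are carried forward independently — the
#' treatment given to FYN-like loci where one probe gains and another
#' loses methylation.
#'
#' @param diff methylation-platform [run_differential()] output.
#' @param ann a [probe_annotation()] table.
#' @return a `data.frame` of class `gene_aggregates`: `gene_symbol`,
#'   `platform`, `direction` (`up`/`down`), `n_significant_probes`,
#'   `mean_delta`, `split_index`, and a list-column `probe_ids` naming the
#'   contributing probes. Unmapped significant probes are attached as
#'   attribute `unmapped`.
#' @export
collapse_methylation <- function(diff, ann) {
  js <- join_significant(diff, ann, "methylation")
  merged <- js$merged
  out <- list()
  for (g in unique(merged$gene_symbol)) {
    rows <- merged[merged$gene_symbol == g, , drop = FALSE]
    ups <- rows[rows$mean_diff > 0, , drop = FALSE]
    downs <- rows[rows$mean_diff < 0, , drop = FALSE]
    groups <- Filter(nrow, list(up = ups, down = downs))
    split <- length(groups) > 1
    for (k in seq_along(groups)) {
      grp <- groups[[k]]
      out[[length(out) + 1L]] <- data.frame(
        gene_symbol = g, platform = "methylation",
        direction = names(groups)[k],
        n_significant_probes = nrow(grp),
        mean_delta = mean(grp$mean_diff),
        split_index = if (split) k - 1L else 0L,
        stringsAsFactors = FALSE
      )
      out[[length(out)]]$probe_ids <- list(grp$feature_id)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_symbol = character(0), platform = character(0),
               direction = character(0), n_significant_probes = integer(0),
               mean_delta = numeric(0), split_index = integer(0),
               probe_ids = I(list()), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "unmapped") <- js$unmapped
  class(res) <- c("gene_aggregates", "data.frame")
  res
}

#' Call gene-level somatic copy number aberrations
#'
#' Implements the adjacent-probe spanning rule: only regions with at least
#' `min_adjacent` consecutive SNP/CN probes that are each significant and
#' share one sign of the tumor-minus-normal log R ratio difference count
#' as an SCNA. Adjacency is defined among a gene's annotated CN probes
#' ordered by genomic coordinate within a chromosome. All qualifying
#' same-direction runs of a gene are merged into a single per-direction
#' call whose `mean_lrr_delta` averages the per-probe mean differences
#' over every contributing probe; opposite-direction runs yield separate
#' gain and loss calls.
#'
#' @param diff cnv-platform [run_differential()] output.
#' @param ann a [probe_annotation()] table.
#' @param min_adjacent minimum run length, at least 2.
#' @return a `data.frame` of class `scna_calls`: `gene_symbol`,
#'   `direction` (`gain`/`loss`), `n_probes`, `mean_lrr_delta`, and a
#'   list-column `run_probe_ids` (probes of all contributing runs, genomic
#'   order). Unmapped significant probes are attached as attribute
#'   `unmapped`.
#' @export
call_scna <- function(diff, ann, min_adjacent = 2L) {
  stopifnot(inherits(diff, "differential_records"),
            inherits(ann, "probe_annotation"))
  if (min_adjacent < 2) stop("min_adjacent must be at least 2")
  cnv_ann <- ann[ann$platform == "cnv", , drop = FALSE]
  sig <- diff[diff$significant, , drop = FALSE]
  unmapped <- setdiff(sig$feature_id, cnv_ann$probe_id)
  if (length(unmapped)) {
    warning("unmapped significant probe(s) excluded: ",
            paste(unmapped, collapse = ", "))
  }
  diff_by_probe <- diff[match(cnv_ann$probe_id, diff$feature_id), ,
                        drop = FALSE]
  out <- list()
  for (g in unique(cnv_ann$gene_symbol)) {
    gi <- which(cnv_ann$gene_symbol == g)
    gi <- gi[order(cnv_ann$chromosome[gi], cnv_ann$start[gi])]
    probes_by_dir <- list(gain = character(0), loss = character(0))
    delta_by_dir <- list(gain = numeric(0), loss = numeric(0))
    for (chr in unique(cnv_ann$chromosome[gi])) {
      ci <- gi[cnv_ann$chromosome[gi] == chr]
      flags <- !is.na(diff_by_probe$significant[ci]) &
        diff_by_probe$significant[ci]
      signs <- ifelse(is.na(diff_by_probe$mean_diff[ci]), 0,
                      diff_by_probe$mean_diff[ci])
      runs <- enumerate_runs(flags, signs)
      runs <- runs[runs$length >= min_adjacent, , drop = FALSE]
      for (r in seq_len(nrow(runs))) {
        idx <- ci[runs$start[r] + seq_len(runs$length[r]) - 1L]
        dir <- if (runs$sign[r] > 0) "gain" else "loss"
        probes_by_dir[[dir]] <- c(probes_by_dir[[dir]],
                                  cnv_ann$probe_id[idx])
        delta_by_dir[[dir]] <- c(delta_by_dir[[dir]],
                                 diff_by_probe$mean_diff[idx])
      }
    }
    for (dir in c("gain", "loss")) {
      if (!length(probes_by_dir[[dir]])) next
      out[[length(out) + 1L]] <- data.frame(
        gene_symbol = g, direction = dir,
        n_probes = length(probes_by_dir[[dir]]),
        mean_lrr_delta = mean(delta_by_dir[[dir]]),
        stringsAsFactors = FALSE
      )
      out[[length(out)]]$run_probe_ids <- list(probes_by_dir[[dir]])
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_symbol = character(0), direction = character(0),
               n_probes = integer(0), mean_lrr_delta = numeric(0),
               run_probe_ids = I(list()), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "unmapped") <- unmapped
  class(res) <- c("scna_calls", "data.frame")
  res
}
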