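#' Spearman rank correlation with exact small-sample p-value
#'
#' `rho` is the Pearson correlation of the (average-tie) ranks. The
#' two-sided p-value is computed by exhaustive enumeration of all `n!`
#' rank permutations when `n <= exact_n_max` (the tail mass of
#' `|rho_perm| >= |rho_obs|`), and by the usual t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' otherwise.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @param exact_n_max largest `n` for which the exact permutation null is
#'   enumerated (default 7; `7! = 5040` permutations).
#' @return a list with `rho`, `p_value`, `n`, and `undefined` (`TRUE` when
#'   either vector has zero rank variance, in which case `rho` and
#'   `p_value` are `NA`).
#' @export
spearman_test <- function(x, y, exact_n_max = 7L) {
  if (length(x) != length(y)) stop("length mismatch")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, undefined = TRUE))
  }
  rho <- cor(rx, ry)
  if (n <= exact_n_max) {
    perms <- all_permutations(n)
    # center/scale once; rho under permutation is a dot product
    zx <- (rx - mean(rx)) / sqrt(sum((rx - mean(rx))^2))
    zy <- (ry - mean(ry)) / sqrt(sum((ry - mean(ry))^2))
    rho_perm <- as.vector(matrix(zy[perms], nrow = nrow(perms)) %*% zx)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- if (is.finite(t)) 2 * pt(-abs(t), df = n - 2) else 0
  }
  list(rho = rho, p_value = p, n = n, undefined = FALSE)
}

# all n! permutations of 1..n, one per row (n <= 8 intended)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    remap <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(remap[sub], nrow = nrow(sub))
  }
  out
}

#' Overlap of two gene sets
#'
#' @param set_a,set_b character vectors of gene symbols (deduplicated).
#' @return a list `n_a_only`, `n_both`, `n_b_only`.
#' @export
overlap_genes <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  both <- intersect(a, b)
  list(n_a_only = length(setdiff(a, b)), n_both = length(both),
       n_b_only = length(setdiff(b, a)))
}

#' Overlap of a study gene list with an external reference list
#'
#' @param study_genes gene symbols found in the study.
#' @param reference_genes gene symbols reported by the reference dataset.
#' @return a list `n_overlap`, `percent` (of the study list, rounded to
#'   1 decimal), and `zero_denominator`.
#' @export
overlap_with_reference <- function(study_genes, reference_genes) {
  study <- unique(study_genes)
  n_overlap <- length(intersect(study, unique(reference_genes)))
  if (!length(study)) {
    return(list(n_overlap = 0L, percent = 0, zero_denominator = TRUE))
  }
  list(n_overlap = n_overlap,
       percent = round(100 * n_overlap / length(study), 1),
       zero_denominator = FALSE)
}

# Per-sample gene-level track: mean over the given feature rows,
# tumor columns of the requested pairs first, then normal columns
# ("pooled"), or tumor only.
pooled_gene_values <- function(mat, feature_ids, pair_ids,
                               samples = "pooled") {
  rows <- match(feature_ids, mat$feature_ids)
  rows <- rows[!is.na(rows)]
  if (!length(rows)) return(NULL)
  t_half <- colMeans(mat$tumor[rows, pair_ids, drop = FALSE], na.rm = TRUE)
  if (samples == "tumor") return(t_half)
  n_half <- colMeans(mat$normal[rows, pair_ids, drop = FALSE], na.rm = TRUE)
  c(t_half, n_half)
}

#' Starburst classification of differentially expressed genes
#'
#' Joins the expression screen with the gene-level methylation and SCNA
#' results and assigns each differentially expressed (DE) gene one
#' methylation category and one copy-number category:
#'
#' * `explained_hyper_down` — expression down, methylation up, and a
#'   significant negative Spearman correlation between the gene's
#'   expression values and its gene-level methylation values;
#'   `explained_hypo_up` is the mirror image.
#' * `explained_gain_up` — expression up, copy number gain, significant
#'   positive correlation with the gene-level log R ratio;
#'   `explained_loss_down` is the mirror (correlation still positive,
#'   expression and copy number falling together).
#' * `overlap_unexplained` — the gene carries a call on that platform but
#'   fails the direction-plus-correlation conjunction.
#' * `no_overlap` — no call on that platform.
#'
#' Gene-level methylation values are the per-sample mean over the
#' contributing significant probes; SCNA values the mean over the probes
#' of the qualifying runs. Correlations pool tumor and normal samples of
#' every shared pair (2n values) unless
#' `config$correlation_samples == "tumor"`. A gene whose significant
#' methylation probes split into both directions is evaluated once per
#' split and labeled explained if any split qualifies.
#'
#' @param expr_diff expression-platform [run_differential()] output.
#' @param meth_agg [collapse_methylation()] output.
#' @param scna [call_scna()] output.
#' @param matrices named list with elements `expression`, `methylation`,
#'   `cnv`, each a [paired_omics_matrix()] (methylation/cnv optional if
#'   the corresponding calls are empty).
#' @param ann a [probe_annotation()] table (maps expression features to
#'   genes).
#' @param config an [analysis_config()].
#' @return a `data.frame` of class `integration_records`, one row per DE
#'   gene: directions, `rho_meth`, `p_meth`, `rho_cn`, `p_cn`,
#'   `coordinate_meth`, `coordinate_cn` (direction agreement before the
#'   correlation filter), `category_meth`, `category_cn`.
#' @export
classify_genes <- function(expr_diff, meth_agg, scna, matrices, ann,
                           config = analysis_config()) {
  stopifnot(inherits(expr_diff, "differential_records"),
            inherits(ann, "probe_annotation"))
  expr_mat <- matrices$expression
  stopifnot(inherits(expr_mat, "paired_omics_matrix"))
  expr_ann <- ann[ann$platform == "expression", , drop = FALSE]
  sig <- expr_diff[expr_diff$significant, , drop = FALSE]
  sig <- merge(sig, expr_ann[, c("probe_id", "gene_symbol")],
               by.x = "feature_id", by.y = "probe_id", sort = FALSE)
  skipped <- character(0)
  out <- list()
  for (g in unique(sig$gene_symbol)) {
    rows <- sig[sig$gene_symbol == g, , drop = FALSE]
    best <- rows[which.min(rows$p_value), , drop = FALSE]
    expr_dir <- best$direction
    rec <- list(gene_symbol = g, expr_direction = expr_dir,
                meth_direction = NA_character_, cn_direction = NA_character_,
                rho_meth = NA_real_, p_meth = NA_real_,
                rho_cn = NA_real_, p_cn = NA_real_,
                coordinate_meth = FALSE, coordinate_cn = FALSE,
                category_meth = "no_overlap", category_cn = "no_overlap")

    # methylation side: evaluate every direction split
    magg <- meth_agg[meth_agg$gene_symbol == g, , drop = FALSE]
    if (nrow(magg)) {
      rec$category_meth <- "overlap_unexplained"
      for (k in seq_len(nrow(magg))) {
        mdir <- magg$direction[k]
        if (is.na(rec$meth_direction)) rec$meth_direction <- mdir
        coordinate <- (expr_dir == "down" && mdir == "up") ||
          (expr_dir == "up" && mdir == "down")
        rec$coordinate_meth <- rec$coordinate_meth || coordinate
        st <- gene_correlation(expr_mat, best$feature_id,
                               matrices$methylation, magg$probe_ids[[k]],
                               config)
        if (is.null(st)) next
        if (is.na(rec$rho_meth)) {
          rec$rho_meth <- st$rho; rec$p_meth <- st$p_value
        }
        explained <- coordinate && !st$undefined && st$rho < 0 &&
          st$p_value < config$spearman_alpha
        if (explained) {
          rec$meth_direction <- mdir
          rec$rho_meth <- st$rho; rec$p_meth <- st$p_value
          rec$category_meth <- if (mdir == "up") "explained_hyper_down"
                               else "explained_hypo_up"
        }
      }
    }

    # copy-number side: per-direction calls
    gcall <- scna[scna$gene_symbol == g, , drop = FALSE]
    if (nrow(gcall)) {
      rec$category_cn <- "overlap_unexplained"
      for (k in seq_len(nrow(gcall))) {
        cdir <- gcall$direction[k]
        if (is.na(rec$cn_direction)) rec$cn_direction <- cdir
        coordinate <- (expr_dir == "up" && cdir == "gain") ||
          (expr_dir == "down" && cdir == "loss")
        rec$coordinate_cn <- rec$coordinate_cn || coordinate
        st <- gene_correlation(expr_mat, best$feature_id,
                               matrices$cnv, gcall$run_probe_ids[[k]],
                               config)
        if (is.null(st)) next
        if (is.na(rec$rho_cn)) {
          rec$rho_cn <- st$rho; rec$p_cn <- st$p_value
        }
        explained <- coordinate && !st$undefined && st$rho > 0 &&
          st$p_value < config$spearman_alpha
        if (explained) {
          rec$cn_direction <- cdir
          rec$rho_cn <- st$rho; rec$p_cn <- st$p_value
          rec$category_cn <- if (cdir == "gain") "explained_gain_up"
                             else "explained_loss_down"
        }
      }
    }
    out[[length(out) + 1L]] <- as.data.frame(rec, stringsAsFactors = FALSE)
  }
  extra <- setdiff(c(meth_agg$gene_symbol, scna$gene_symbol),
                   c(sig$gene_symbol, expr_ann$gene_symbol))
  if (length(extra)) {
    warning("gene(s) with methylation/SCNA calls absent from the ",
            "expression annotation, skipped: ",
            paste(unique(extra), collapse = ", "))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_symbol = character(0), expr_direction = character(0),
               meth_direction = character(0), cn_direction = character(0),
               rho_meth = numeric(0), p_meth = numeric(0),
               rho_cn = numeric(0), p_cn = numeric(0),
               coordinate_meth = logical(0), coordinate_cn = logical(0),
               category_meth = character(0), category_cn = character(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("integration_records", "data.frame")
  res
}

# Spearman between a gene's expression track and its gene-level track on
# another platform, over the pairs shared by both matrices.
gene_correlation <- function(expr_mat, expr_feature, other_mat, probe_ids,
                             config) {
  if (is.null(other_mat)) return(NULL)
  pairs <- intersect(expr_mat$pair_ids, other_mat$pair_ids)
  if (length(pairs) < 3) return(NULL)
  ev <- pooled_gene_values(expr_mat, expr_feature, pairs,
                           config$correlation_samples)
  ov <- pooled_gene_values(other_mat, probe_ids, pairs,
                           config$correlation_samples)
  if (is.null(ev) || is.null(ov)) return(NULL)
  spearman_test(ev, ov)
}

#' Cohort contribution report from integration records
#'
#' Counts, over the DE genes, platform overlaps and explained genes and
#' derives the explained fractions (see [contribution_report()]). The
#' coordinate-direction counts before the correlation filter are attached
#' as attributes `n_meth_coordinate` and `n_cn_coordinate` so both
#' readings of "explained" can be audited.
#'
#' @param records [classify_genes()] output.
#' @return a [contribution_report()].
#' @export
contribution <- function(records) {
  stopifnot(inherits(records, "integration_records"))
  meth_exp <- records$category_meth %in%
    c("explained_hyper_down", "explained_hypo_up")
  cn_exp <- records$category_cn %in%
    c("explained_gain_up", "explained_loss_down")
  rep <- contribution_report(
    n_de_genes = nrow(records),
    n_meth_overlap = sum(records$category_meth != "no_overlap"),
    n_meth_explained = sum(meth_exp),
    n_cn_overlap = sum(records$category_cn != "no_overlap"),
    n_cn_explained = sum(cn_exp),
    n_both_explained = sum(meth_exp & cn_exp)
  )
  attr(rep, "n_meth_coordinate") <- sum(records$coordinate_meth)
  attr(rep, "n_cn_coordinate") <- sum(records$coordinate_cn)
  rep
}
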