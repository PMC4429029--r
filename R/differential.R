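#' Paired t-test on one feature
#'
#' One-sample Student t-test on the within-pair differences
#' `d = tumor - normal`: `t = mean(d) / (sd(d) / sqrt(n))`, two-sided
#' p-value from the t distribution with `n - 1` degrees of freedom.
#' Degenerate zero-variance differences are handled explicitly: if all
#' differences are exactly 0 the result is `t = 0, p = 1`; if the
#' differences are constant but nonzero the p-value is reported as 0 and
#' the record flagged `degenerate` rather than producing an infinite
#' statistic silently.
#'
#' @param tumor,normal numeric vectors of equal length `n >= 2`; pairs with
#'   a missing value in either half are dropped before testing
#'   (complete-pairs analysis).
#' @return a list with `n_complete_pairs`, `mean_diff`, `t_stat`,
#'   `p_value`, `degenerate`.
#' @export
paired_t_test <- function(tumor, normal) {
  if (length(tumor) != length(normal)) stop("length mismatch")
  d <- tumor - normal
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2) stop("insufficient pairs: need at least 2 complete pairs")
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (m == 0) {
      return(list(n_complete_pairs = n, mean_diff = 0, t_stat = 0,
                  p_value = 1, degenerate = FALSE))
    }
    return(list(n_complete_pairs = n, mean_diff = m,
                t_stat = sign(m) * Inf, p_value = 0, degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  list(n_complete_pairs = n, mean_diff = m, t_stat = t,
       p_value = 2 * pt(-abs(t), df = n - 1), degenerate = FALSE)
}

#' Bonferroni significance threshold
#'
#' Per-test threshold `alpha / m` controlling the family-wise error rate at
#' `alpha` over `m` tests. With `alpha = 0.05` this gives 4.5e-5 for 1,108
#' transcripts, 1.3e-6 for 38,179 methylation probes and 1.48e-6 for
#' 33,855 SNP/CN probes.
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param m number of tests, at least 1.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  if (!is.numeric(m) || m < 1 || m != round(m)) {
    stop("m must be a positive integer")
  }
  alpha / m
}

#' Benjamini-Hochberg step-up rejections
#'
#' Rejects the `k` smallest p-values where
#' `k = max { i : p_(i) <= i * alpha / m }`, controlling the false
#' discovery rate at `alpha` under independence.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param alpha target FDR in (0, 1).
#' @return logical vector: `TRUE` where the hypothesis is rejected.
#' @export
bh_fdr <- function(p_values, alpha) {
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  if (!m) return(logical(0))
  o <- order(p_values)
  passes <- p_values[o] <= seq_len(m) * alpha / m
  k <- if (any(passes)) max(which(passes)) else 0L
  rej <- logical(m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

#' Per-feature paired differential testing
#'
#' Applies the paired t-test to every feature of a [paired_omics_matrix()]
#' and controls multiplicity over the features actually tested: features
#' left with fewer than 2 complete pairs are set aside as untestable and
#' excluded from the multiplicity count `m`. Under Bonferroni the
#' significance threshold is `alpha_fwer / m`; under `"bh"` the
#' Benjamini-Hochberg step-up rule is applied at `alpha_fwer`.
#'
#' @param matrix a [paired_omics_matrix()].
#' @param config an [analysis_config()].
#' @return a `data.frame` of class `differential_records` with one row per
#'   tested feature: `feature_id`, `n_complete_pairs`, `mean_diff`,
#'   `t_stat`, `p_value`, `direction` (`up`/`down`/`none`), `significant`,
#'   `threshold_used`, `degenerate`. Untestable feature ids are attached as
#'   attribute `untestable`; the platform as attribute `platform`.
#' @export
run_differential <- function(matrix, config = analysis_config()) {
  stopifnot(inherits(matrix, "paired_omics_matrix"),
            inherits(config, "analysis_config"))
  d <- matrix$tumor - matrix$normal
  n_pairs <- rowSums(!is.na(d))
  untestable <- matrix$feature_ids[n_pairs < 2]
  keep <- n_pairs >= 2
  d <- d[keep, , drop = FALSE]
  n <- n_pairs[keep]
  m <- sum(keep)

  if (m == 0) {
    res <- data.frame(feature_id = character(0), n_complete_pairs = integer(0),
                      mean_diff = numeric(0), t_stat = numeric(0),
                      p_value = numeric(0), direction = character(0),
                      significant = logical(0), threshold_used = numeric(0),
                      degenerate = logical(0), stringsAsFactors = FALSE)
  } else {
    mu <- rowMeans(d, na.rm = TRUE)
    ss <- rowSums((d - mu)^2, na.rm = TRUE)
    s <- sqrt(ss / (n - 1))
    t <- ifelse(s > 0, mu / (s / sqrt(n)),
                ifelse(mu == 0, 0, sign(mu) * Inf))
    p <- ifelse(is.finite(t), 2 * pt(-abs(t), df = n - 1), 0)
    degenerate <- s == 0 & mu != 0
    res <- data.frame(
      feature_id = matrix$feature_ids[keep], n_complete_pairs = as.integer(n),
      mean_diff = mu, t_stat = t, p_value = p,
      direction = "none", significant = FALSE, threshold_used = NA_real_,
      degenerate = degenerate, stringsAsFactors = FALSE
    )
    if (config$correction == "bonferroni") {
      thr <- bonferroni_threshold(config$alpha_fwer, m)
      res$significant <- res$p_value < thr
      res$threshold_used <- thr
    } else {
      res$significant <- bh_fdr(res$p_value, config$alpha_fwer)
      kmax <- sum(res$significant)
      res$threshold_used <- kmax * config$alpha_fwer / m
    }
    # degenerate constant nonzero differences are flagged, never called
    res$significant[res$degenerate] <- FALSE
    res$direction <- ifelse(res$significant & res$mean_diff > 0, "up",
                            ifelse(res$significant & res$mean_diff < 0,
                                   "down", "none"))
    rownames(res) <- NULL
  }
  attr(res, "untestable") <- untestable
  attr(res, "platform") <- matrix$platform
  attr(res, "m_tested") <- m
  class(res) <- c("differential_records", "data.frame")
  res
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two labelings of the same items:
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  expected <- sum_a * sum_b / total
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (max_idx - expected)
}

#' Tumor/normal cluster-separation score
#'
#' Checks whether the significant features alone separate tumor from
#' normal samples, as in an exploratory heatmap: the `2n` samples are
#' stacked as observations over the significant features, agglomeratively
#' clustered (distance `1 - Pearson` between sample profiles; average
#' linkage by default), the tree is cut at 2 clusters and the adjusted
#' Rand index against the true tumor/normal labels is returned.
#'
#' @param matrix a [paired_omics_matrix()] with at least 2 pairs.
#' @param significant_features character vector of at least 2 feature ids.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return separation score in `[-1, 1]`; 1 means a perfect split.
#' @export
cluster_separation <- function(matrix, significant_features,
                               linkage = "average") {
  stopifnot(inherits(matrix, "paired_omics_matrix"))
  feats <- intersect(significant_features, matrix$feature_ids)
  if (length(feats) < 2) {
    stop("not computable: need at least 2 significant features")
  }
  if (length(matrix$pair_ids) < 2) {
    stop("need at least 2 samples per group")
  }
  x <- cbind(matrix$tumor[feats, , drop = FALSE],
             matrix$normal[feats, , drop = FALSE])
  labels <- rep(c("tumor", "normal"), each = length(matrix$pair_ids))
  cors <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  cors[is.na(cors)] <- 0
  h <- hclust(as.dist(1 - cors), method = linkage)
  adjusted_rand_index(cutree(h, k = 2), labels)
}
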