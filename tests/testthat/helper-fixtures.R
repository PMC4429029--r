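# shared builders and independent oracles for the test suite

# a paired matrix from two plain matrices with default ids
toy_matrix <- function(tumor, normal, platform = "expression",
                       features = NULL, pairs = NULL) {
  tumor <- as.matrix(tumor); normal <- as.matrix(normal)
  if (is.null(features)) features <- sprintf("f%d", seq_len(nrow(tumor)))
  if (is.null(pairs)) pairs <- sprintf("s%d", seq_len(ncol(tumor)))
  dimnames(tumor) <- list(features, pairs)
  dimnames(normal) <- list(features, pairs)
  paired_omics_matrix(tumor, normal, platform)
}

# hand-built differential records with the class attribute set
make_diff <- function(feature_id, mean_diff, significant,
                      p_value = ifelse(significant, 1e-8, 0.5)) {
  n <- length(feature_id)
  res <- data.frame(
    feature_id = feature_id, n_complete_pairs = rep_len(10L, n),
    mean_diff = mean_diff, t_stat = mean_diff * 10,
    p_value = rep_len(p_value, n),
    direction = ifelse(significant & mean_diff > 0, "up",
                       ifelse(significant & mean_diff < 0, "down", "none")),
    significant = significant, threshold_used = rep_len(1e-6, n),
    degenerate = rep_len(FALSE, n),
    stringsAsFactors = FALSE
  )
  class(res) <- c("differential_records", "data.frame")
  res
}

simple_annotation <- function(probe_id, platform, gene_symbol,
                              chromosome = "chr1",
                              start = seq_along(probe_id) * 100L) {
  probe_annotation(
    chromosome = chromosome, start = start, end = start + 50L,
    probe_id = probe_id, platform = platform, gene_symbol = gene_symbol
  )
}

# --- independent oracles -------------------------------------------------

# maximal significant same-sign runs by O(n^2) interval enumeration
runs_oracle <- function(flags, signs) {
  s <- sign(signs)
  ok <- as.logical(flags) & s != 0
  valid <- function(i, j) {
    all(ok[i:j]) && length(unique(s[i:j])) == 1
  }
  out <- data.frame(start = integer(0), length = integer(0),
                    sign = numeric(0))
  n <- length(flags)
  for (i in seq_len(n)) for (j in i:n) {
    if (!valid(i, j)) next
    left_max <- i == 1 || !ok[i - 1] || s[i - 1] != s[i]
    right_max <- j == n || !ok[j + 1] || s[j + 1] != s[i]
    if (left_max && right_max) {
      out <- rbind(out, data.frame(start = i, length = j - i + 1L,
                                   sign = s[i]))
    }
  }
  out[order(out$start), , drop = FALSE]
}

# next permutation in lexicographic order; NULL after the last one
next_perm <- function(p) {
  n <- length(p)
  i <- n - 1L
  while (i >= 1L && p[i] >= p[i + 1L]) i <- i - 1L
  if (i < 1L) return(NULL)
  j <- n
  while (p[j] <= p[i]) j <- j - 1L
  tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
  p[(i + 1L):n] <- rev(p[(i + 1L):n])
  p
}

# exact two-sided Spearman p by walking all permutations lexicographically
spearman_exact_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- cor(rx, ry)
  p <- seq_along(y)
  hits <- 0L; total <- 0L
  while (!is.null(p)) {
    total <- total + 1L
    if (abs(cor(rx, ry[p])) >= abs(obs) - 1e-12) hits <- hits + 1L
    p <- next_perm(p)
  }
  list(rho = obs, p_value = hits / total)
}
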