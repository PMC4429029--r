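test_that("spearman handles monotone, reversed and tied inputs", {
  r <- spearman_test(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(r$rho, 1)
  r <- spearman_test(c(1, 2, 3), c(3, 2, 1))
  expect_equal(r$rho, -1)
  # rho = 1 - 6 * sum(d^2) / (n(n^2-1)) with d = (0,-1,1,-1,1)
  r <- spearman_test(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  expect_equal(r$rho, 0.8)
  w <- spearman_exact_oracle(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  expect_equal(r$p_value, w$p_value)
  # constant vector: rank variance zero, flagged undefined
  r <- spearman_test(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_true(r$undefined)
  expect_true(is.na(r$rho))
  expect_error(spearman_test(1:2, 1:2), "at least 3")
})

test_that("exact small-n p-values match the permutation oracle", {
  set.seed(77)
  cases <- list(
    list(x = c(1, 2, 3, 4, 5), y = c(1, 3, 2, 5, 4)),
    list(x = c(1, 2, 3, 4), y = c(4, 3, 2, 1)),
    list(x = c(2, 1, 4, 3, 6, 5), y = c(1, 2, 3, 4, 5, 6))
  )
  for (i in 1:15) {
    n <- sample(3:6, 1)
    cases[[length(cases) + 1]] <- list(x = rnorm(n), y = rnorm(n))
  }
  for (cs in cases) {
    got <- spearman_test(cs$x, cs$y)
    want <- spearman_exact_oracle(cs$x, cs$y)
    expect_equal(got$rho, want$rho)
    expect_equal(got$p_value, want$p_value)
  }
})

test_that("large-n p-values agree with the t approximation of cor.test", {
  set.seed(78)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    got <- spearman_test(x, y)
    want <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(got$rho, unname(want$estimate), tolerance = 1e-12)
    expect_equal(got$p_value, want$p.value, tolerance = 1e-9)
  }
})

test_that("gene set overlaps match brute-force membership scans", {
  r <- overlap_genes(c("g1", "g2"), c("g2", "g3"))
  expect_equal(r, list(n_a_only = 1L, n_both = 1L, n_b_only = 1L))
  r <- overlap_genes(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(r, list(n_a_only = 0L, n_both = 3L, n_b_only = 0L))
  set.seed(9)
  for (i in 1:50) {
    a <- sample(paste0("g", 1:30), sample(0:20, 1))
    b <- sample(paste0("g", 1:30), sample(0:20, 1))
    r <- overlap_genes(a, b)
    expect_equal(r$n_both, sum(vapply(unique(a), `%in%`, logical(1), b)))
    expect_equal(r$n_a_only + r$n_both, length(unique(a)))
    expect_equal(r$n_b_only + r$n_both, length(unique(b)))
  }
})

test_that("reference overlap reports rounded percentages", {
  study <- paste0("g", 1:252)
  reference <- c(paste0("g", 1:200), paste0("x", 1:50))
  r <- overlap_with_reference(study, reference)
  expect_equal(r$n_overlap, 200L)
  expect_equal(r$percent, 79.4)
  expect_equal(overlap_with_reference(c("a"), c("b"))$percent, 0)
  r <- overlap_with_reference(c("a", "b"), c("a", "b", "c"))
  expect_equal(r$percent, 100)
  expect_true(overlap_with_reference(character(0), "a")$zero_denominator)
})

make_classify_fixture <- function() {
  # 6 pairs; GENE1: expr down, meth up, tightly anti-correlated (explained)
  # GENE2: expr up, meth up (discordant); GENE3: expr up, no meth call
  set.seed(123)
  n <- 6
  base <- rnorm(n, 8, 1)
  e1_n <- base + rnorm(n, 0, 0.1); e1_t <- base - 2 + rnorm(n, 0, 0.1)
  m1_n <- -e1_n + rnorm(n, 0, 0.05); m1_t <- -e1_t + rnorm(n, 0, 0.05)
  e2_n <- base + rnorm(n, 0, 0.1); e2_t <- base + 2 + rnorm(n, 0, 0.1)
  m2_n <- rnorm(n, 0, 0.1); m2_t <- m2_n + 1
  e3_n <- base; e3_t <- base + 1.5

  expr <- toy_matrix(rbind(e1_t, e2_t, e3_t), rbind(e1_n, e2_n, e3_n),
                     features = c("tx1", "tx2", "tx3"))
  meth <- toy_matrix(rbind(m1_t, m2_t), rbind(m1_n, m2_n),
                     platform = "methylation", features = c("m1", "m2"))
  ann <- simple_annotation(c("tx1", "tx2", "tx3", "m1", "m2"),
                           c(rep("expression", 3), rep("methylation", 2)),
                           c("GENE1", "GENE2", "GENE3", "GENE1", "GENE2"))
  expr_diff <- make_diff(c("tx1", "tx2", "tx3"), c(-2, 2, 1.5),
                         rep(TRUE, 3))
  meth_diff <- make_diff(c("m1", "m2"), c(2, 1), rep(TRUE, 2))
  agg <- collapse_methylation(meth_diff, ann)
  scna <- call_scna(make_diff(character(0), numeric(0), logical(0)),
                    ann, 2)
  list(expr = expr, meth = meth, ann = ann, expr_diff = expr_diff,
       agg = agg, scna = scna)
}

test_that("classification applies the direction-plus-correlation rule", {
  fx <- make_classify_fixture()
  rec <- classify_genes(fx$expr_diff, fx$agg, fx$scna,
                        list(expression = fx$expr, methylation = fx$meth),
                        fx$ann, analysis_config())
  rec <- rec[order(rec$gene_symbol), ]
  expect_equal(rec$gene_symbol, c("GENE1", "GENE2", "GENE3"))
  # explained: expr down + meth up + significant negative rho
  expect_equal(rec$category_meth[1], "explained_hyper_down")
  expect_lt(rec$rho_meth[1], 0)
  expect_lt(rec$p_meth[1], 0.05)
  # discordant direction can never be explained
  expect_equal(rec$category_meth[2], "overlap_unexplained")
  expect_false(rec$coordinate_meth[2])
  # no methylation call at all
  expect_equal(rec$category_meth[3], "no_overlap")
  # no SCNA calls anywhere
  expect_true(all(rec$category_cn == "no_overlap"))
  # categories partition the DE genes per platform
  expect_equal(nrow(rec), length(unique(rec$gene_symbol)))
})

test_that("contribution counts follow the report definitions", {
  fx <- make_classify_fixture()
  rec <- classify_genes(fx$expr_diff, fx$agg, fx$scna,
                        list(expression = fx$expr, methylation = fx$meth),
                        fx$ann, analysis_config())
  rep <- contribution(rec)
  expect_equal(rep$n_de_genes, 3L)
  expect_equal(rep$n_meth_overlap, 2L)
  expect_equal(rep$n_meth_explained, 1L)
  expect_equal(rep$n_cn_explained, 0L)
  expect_equal(rep$frac_meth, 1 / 3)
  expect_equal(rep$frac_union, 1 / 3)

  # all genes methylation-explained
  rec2 <- rec
  rec2$category_meth <- "explained_hyper_down"
  rep2 <- contribution(rec2)
  expect_equal(rep2$frac_meth, 1)
  expect_equal(rep2$frac_union, 1)

  # empty input flags the zero denominator
  rec0 <- rec[0, ]
  class(rec0) <- class(rec)
  expect_true(contribution(rec0)$zero_denominator)
})

test_that("explained fractions are monotone when a gene becomes explained", {
  fx <- make_classify_fixture()
  rec <- classify_genes(fx$expr_diff, fx$agg, fx$scna,
                        list(expression = fx$expr, methylation = fx$meth),
                        fx$ann, analysis_config())
  before <- contribution(rec)
  rec$category_meth[rec$category_meth == "overlap_unexplained"] <-
    "explained_hypo_up"
  after <- contribution(rec)
  expect_gte(after$frac_meth, before$frac_meth)
  expect_gte(after$frac_union, before$frac_union)
  expect_lte(after$frac_union, after$frac_meth + after$frac_cn)
})
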