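test_that("enumerate_runs finds maximal same-sign runs", {
  r <- enumerate_runs(c(TRUE, TRUE, TRUE, TRUE), c(1, 2, -1, -3))
  expect_equal(r$start, c(1L, 3L))
  expect_equal(r$length, c(2L, 2L))
  expect_equal(r$sign, c(1, -1))

  expect_equal(nrow(enumerate_runs(rep(FALSE, 5), rep(1, 5))), 0)

  r <- enumerate_runs(c(FALSE, TRUE, FALSE), c(0, -2, 0))
  expect_equal(r$start, 2L)
  expect_equal(r$length, 1L)
  expect_equal(r$sign, -1)
})

test_that("enumerate_runs matches brute-force interval enumeration", {
  set.seed(202)
  for (i in 1:1000) {
    n <- sample(1:15, 1)
    flags <- runif(n) < 0.6
    signs <- sample(c(-2, -1, 1, 2), n, replace = TRUE)
    got <- enumerate_runs(flags, signs)
    want <- runs_oracle(flags, signs)
    expect_equal(got$start, want$start)
    expect_equal(got$length, want$length)
    expect_equal(got$sign, want$sign)
  }
})

test_that("methylation collapse averages same-direction significant probes", {
  diff <- make_diff(paste0("m", 1:4), c(0.2, 0.3, 0.4, 0.9),
                    c(TRUE, TRUE, TRUE, FALSE))
  ann <- simple_annotation(paste0("m", 1:4), "methylation", "GENE1")
  agg <- collapse_methylation(diff, ann)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$direction, "up")
  expect_equal(agg$mean_delta, 0.3)
  expect_equal(agg$n_significant_probes, 3L)
  expect_equal(agg$split_index, 0L)
  expect_setequal(agg$probe_ids[[1]], c("m1", "m2", "m3"))
})

test_that("opposite-direction probes split into two carried records", {
  diff <- make_diff(c("m1", "m2"), c(0.2, -0.5), c(TRUE, TRUE))
  ann <- simple_annotation(c("m1", "m2"), "methylation", "FYN")
  agg <- collapse_methylation(diff, ann)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$direction, c("up", "down"))
  expect_equal(agg$mean_delta, c(0.2, -0.5))
  expect_equal(agg$split_index, c(0L, 1L))
})

test_that("genes without significant probes emit nothing; unmapped probes warn", {
  diff <- make_diff(c("m1", "m2"), c(0.2, 0.4), c(FALSE, FALSE))
  ann <- simple_annotation(c("m1", "m2"), "methylation", "GENE1")
  expect_equal(nrow(collapse_methylation(diff, ann)), 0)

  diff <- make_diff(c("m1", "mX"), c(0.2, 0.4), c(TRUE, TRUE))
  expect_warning(agg <- collapse_methylation(diff, ann), "unmapped")
  expect_equal(nrow(agg), 1)
  expect_equal(attr(agg, "unmapped"), "mX")
})

test_that("probe accounting: every significant annotated probe counted once", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(4:20, 1)
    probes <- paste0("m", seq_len(n))
    genes <- sample(paste0("G", 1:3), n, replace = TRUE)
    diff <- make_diff(probes, rnorm(n), runif(n) < 0.5)
    ann <- simple_annotation(probes, "methylation", genes)
    agg <- collapse_methylation(diff, ann)
    expect_equal(sum(agg$n_significant_probes), sum(diff$significant))
  }
})

test_that("SCNA calls require at least 2 adjacent same-sign significant probes", {
  ann <- simple_annotation(paste0("c", 1:4), "cnv", "GENE1")

  # [T,T,F,T] all positive: only the adjacent pair is called
  diff <- make_diff(paste0("c", 1:4), c(0.4, 0.6, 0.5, 0.5),
                    c(TRUE, TRUE, FALSE, TRUE))
  calls <- call_scna(diff, ann, 2)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$direction, "gain")
  expect_equal(calls$run_probe_ids[[1]], c("c1", "c2"))
  expect_equal(calls$mean_lrr_delta, 0.5)

  # no significant probes -> no call
  diff <- make_diff(paste0("c", 1:3)[1:3], c(0.4, 0.6, 0.5), rep(FALSE, 3))
  expect_equal(nrow(call_scna(diff, simple_annotation(paste0("c", 1:3),
                                                      "cnv", "GENE1"), 2)), 0)

  # [T,T,T] signs [+,+,-]: gain call from 2 probes, isolated loss excluded
  diff <- make_diff(paste0("c", 1:3), c(0.4, 0.6, -0.5), rep(TRUE, 3))
  calls <- call_scna(diff, simple_annotation(paste0("c", 1:3), "cnv",
                                             "GENE1"), 2)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$direction, "gain")
  expect_equal(calls$n_probes, 2L)
  expect_equal(calls$mean_lrr_delta, 0.5)
})

test_that("same-direction runs merge per gene; opposite directions stay separate", {
  ann <- simple_annotation(paste0("c", 1:8), "cnv", "GENE1")
  diff <- make_diff(paste0("c", 1:8),
                    c(0.4, 0.6, -0.5, -0.3, 0.2, 0.4, -0.1, 0.9),
                    c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  calls <- call_scna(diff, ann, 2)
  expect_equal(nrow(calls), 2)
  gain <- calls[calls$direction == "gain", ]
  loss <- calls[calls$direction == "loss", ]
  # two gain runs (c1,c2) and (c5,c6) merged; isolated c8 excluded
  expect_equal(gain$run_probe_ids[[1]], c("c1", "c2", "c5", "c6"))
  expect_equal(gain$mean_lrr_delta, mean(c(0.4, 0.6, 0.2, 0.4)))
  expect_equal(loss$run_probe_ids[[1]], c("c3", "c4"))
  expect_equal(loss$mean_lrr_delta, -0.4)
})

test_that("deleting one probe of a length-2 run removes the call", {
  ann <- simple_annotation(paste0("c", 1:4), "cnv", "GENE1")
  diff <- make_diff(paste0("c", 1:4), c(0.4, 0.6, 0.1, 0.2),
                    c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(nrow(call_scna(diff, ann, 2)), 1)
  for (drop in c("c1", "c2")) {
    d2 <- diff[diff$feature_id != drop, ]
    class(d2) <- class(diff)
    expect_equal(nrow(call_scna(d2, ann, 2)), 0)
  }
})

test_that("runs never span chromosomes and respect min_adjacent", {
  ann <- probe_annotation(
    chromosome = c("chr1", "chr1", "chr2", "chr2"),
    start = c(100L, 200L, 100L, 200L), end = c(150L, 250L, 150L, 250L),
    probe_id = paste0("c", 1:4), platform = "cnv", gene_symbol = "GENE1"
  )
  diff <- make_diff(paste0("c", 1:4), rep(0.5, 4),
                    c(FALSE, TRUE, TRUE, FALSE))
  # the two significant probes are adjacent in input order but on
  # different chromosomes: no call
  expect_equal(nrow(call_scna(diff, ann, 2)), 0)

  diff <- make_diff(paste0("c", 1:4), rep(0.5, 4), rep(TRUE, 4))
  expect_equal(nrow(call_scna(diff, ann, 2)), 1)   # merged gain, 4 probes
  expect_equal(nrow(call_scna(diff, ann, 3)), 0)   # each run only length 2
  expect_error(call_scna(diff, ann, 1), "at least 2")
})
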