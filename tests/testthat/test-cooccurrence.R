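test_that("chi-square statistic matches hand-evaluated closed forms", {
  # observed equals expected: statistic 0, p 1, not enriched
  r <- chi_square_2x2(10, 20, 50, 100)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$enriched)

  # hand-evaluated: 100 * (20*60 - 10*10)^2 / (30*70*30*70)
  r2 <- chi_square_2x2(20, 30, 30, 100)
  expect_equal(r2$statistic, 121e6 / 4.41e6, tolerance = 1e-12)
  expect_true(r2$enriched)
  expect_true(r2$p_value < 1e-5)

  expect_error(chi_square_2x2(0, 0, 10, 100),
               class = "adrsub_degenerate_table_error")
  expect_error(chi_square_2x2(30, 20, 50, 100),
               class = "adrsub_validation_error")
})

test_that("statistic agrees with the textbook sum((O-E)^2/E) form and with stats::chisq.test on random tables", {
  set.seed(404)
  for (i in 1:1000) {
    N <- sample(50:500, 1)
    n_d <- sample(1:(N - 1), 1)
    n_e <- sample(1:(N - 1), 1)
    lo <- max(0, n_d + n_e - N)
    n11 <- sample(lo:min(n_d, n_e), 1)
    res <- chi_square_2x2(n11, n_d, n_e, N)
    O <- matrix(c(n11, n_d - n11, n_e - n11, N - n_d - n_e + n11), 2)
    E <- outer(rowSums(O), colSums(O)) / N
    expect_equal(res$statistic, sum((O - E)^2 / E), tolerance = 1e-9)
    # transposition invariance (drug/event role swap)
    swapped <- chi_square_2x2(n11, n_e, n_d, N)
    expect_equal(res$statistic, swapped$statistic, tolerance = 1e-12)
  }
  # independent library oracle on a handful of cases
  for (tbl in list(c(20, 30, 30, 100), c(5, 40, 10, 200),
                   c(12, 25, 60, 120))) {
    res <- chi_square_2x2(tbl[1], tbl[2], tbl[3], tbl[4])
    O <- matrix(c(tbl[1], tbl[2] - tbl[1], tbl[3] - tbl[1],
                  tbl[4] - tbl[2] - tbl[3] + tbl[1]), 2)
    ct <- suppressWarnings(stats::chisq.test(O, correct = FALSE))
    expect_equal(res$statistic, unname(ct$statistic), tolerance = 1e-9)
    expect_equal(res$p_value, ct$p.value, tolerance = 1e-9)
    ct_y <- suppressWarnings(stats::chisq.test(O, correct = TRUE))
    expect_equal(chi_square_2x2(tbl[1], tbl[2], tbl[3], tbl[4],
                                correction = TRUE)$statistic,
                 unname(ct_y$statistic), tolerance = 1e-9)
  }
})

test_that("enrichment is monotone in the joint count at fixed margins", {
  prev <- FALSE
  for (n11 in 0:30) {
    r <- chi_square_2x2(n11, 30, 40, 200)
    if (prev) expect_true(r$enriched)
    prev <- r$enriched
  }
})

test_that("provider scores 1 exactly when a significant enriched interaction exists", {
  doc <- exchange_input(list(tiny_pair()))

  # strongly enriched in one resource
  w <- manual_world(corpus = list(medline = tiny_corpus(20, 30, 30, 100)))
  out <- run_cooccurrence_provider(doc, w)
  expect_identical(out$signals[[1]]$score, 1)
  expect_identical(out$signals[[1]]$annotations[[1]]$kind, "resource")
  expect_identical(out$signals[[1]]$annotations[[1]]$value, "medline")

  # observed equals expected everywhere: never significant
  w0 <- manual_world(corpus = list(medline = tiny_corpus(10, 20, 50, 100),
                                   drugbank = tiny_corpus(10, 20, 50, 100)))
  expect_identical(run_cooccurrence_provider(doc, w0)$signals[[1]]$score, 0)

  # significantly depleted co-occurrence does not count as found
  wd <- manual_world(corpus = list(medline = tiny_corpus(0, 40, 40, 100)))
  out_d <- run_cooccurrence_provider(doc, wd)
  expect_identical(out_d$signals[[1]]$score, 0)

  # unindexed pair: score 0 with a not-indexed note
  we <- manual_world(corpus = list(medline = corpus_counts(
    "medline", 100, c(C01AA05 = 10), c(EV09 = 10),
    data.frame(drug = character(0), event = character(0),
               count = numeric(0), stringsAsFactors = FALSE))))
  out_e <- run_cooccurrence_provider(doc, we)
  expect_identical(out_e$signals[[1]]$score, 0)
  expect_identical(out_e$signals[[1]]$annotations[[1]]$value, "not-indexed")
})

test_that("no usable resource index yields monitoring code 41", {
  out <- run_cooccurrence_provider(exchange_input(list(tiny_pair())),
                                   manual_world(corpus = NULL))
  expect_identical(out$monitoring$code, 41L)
})

test_that("alpha must be a valid significance level", {
  w <- manual_world(corpus = list(medline = tiny_corpus(20, 30, 30, 100)))
  doc <- exchange_input(list(tiny_pair()))
  expect_error(run_cooccurrence_provider(doc, w, alpha = 0),
               class = "adrsub_config_error")
  expect_error(run_cooccurrence_provider(doc, w, alpha = 1),
               class = "adrsub_config_error")
})
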