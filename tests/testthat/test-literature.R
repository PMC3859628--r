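test_that("publication counting follows the subheading match rule", {
  pair <- tiny_pair()
  expect_identical(
    count_supporting_publications(pair, tiny_literature_index(0))$n, 0L)

  idx <- tiny_literature_index(3)
  res <- count_supporting_publications(pair, idx)
  expect_identical(res$n, 3L)
  expect_identical(res$publication_ids,
                   sprintf("2000%04d", 1:3))
})

test_that("qualifier combinations decide the match, verified by enumeration", {
  # brute-force oracle over all (drug qualifier, event qualifier) combos
  quals <- c(NA, "adverse effects", "chemically induced")
  combos <- expand.grid(dq = quals, eq = quals, stringsAsFactors = FALSE)
  pair <- tiny_pair()
  for (i in seq_len(nrow(combos))) {
    rec <- data.frame(descriptor = c("D_A10BA02", "E_EV01"),
                      qualifier = c(combos$dq[i], combos$eq[i]),
                      stringsAsFactors = FALSE)
    idx <- literature_index(list(p1 = rec),
                            drug_map = c(A10BA02 = "D_A10BA02"),
                            event_map = c(EV01 = "E_EV01"))
    # oracle: drug qualified "adverse effects" with event present, or
    # event qualified "chemically induced" with drug present
    expect_either <- identical(combos$dq[i], "adverse effects") ||
      identical(combos$eq[i], "chemically induced")
    expect_both <- identical(combos$dq[i], "adverse effects") &&
      identical(combos$eq[i], "chemically induced")
    expect_identical(
      count_supporting_publications(pair, idx, match_rule("either"))$n,
      as.integer(expect_either), info = paste("either", i))
    expect_identical(
      count_supporting_publications(pair, idx, match_rule("both"))$n,
      as.integer(expect_both), info = paste("both", i))
  }
})

test_that("pharmacological-action expansion broadens the drug descriptor set", {
  pair <- tiny_pair()
  rec <- data.frame(descriptor = c("PA_class", "E_EV01"),
                    qualifier = c("adverse effects", NA),
                    stringsAsFactors = FALSE)
  idx <- literature_index(list(p1 = rec),
                          drug_map = c(A10BA02 = "D_A10BA02"),
                          event_map = c(EV01 = "E_EV01"),
                          pharm_actions = list(D_A10BA02 = "PA_class"))
  expect_identical(count_supporting_publications(pair, idx)$n, 0L)
  expect_identical(
    count_supporting_publications(
      pair, idx, match_rule(use_pharmacological_action = TRUE))$n, 1L)
})

test_that("score_from_count is the stepped 0 / 0.5 / 1 rule and is monotone", {
  expect_identical(as.numeric(score_from_count(0)), 0)
  expect_identical(as.numeric(score_from_count(1)), 0.5)
  expect_identical(as.numeric(score_from_count(2)), 0.5)
  expect_identical(as.numeric(score_from_count(3)), 1)
  expect_identical(as.numeric(score_from_count(100)), 1)
  expect_error(score_from_count(-1), class = "adrsub_validation_error")
  s <- vapply(0:1000, function(n) as.numeric(score_from_count(n)),
              numeric(1))
  expect_true(all(diff(s) >= 0))
  expect_setequal(unique(s), c(0, 0.5, 1))
})

test_that("provider annotates positive scores with one pubmed link per publication", {
  doc <- exchange_input(list(tiny_pair()))
  out <- run_literature_provider(doc, manual_world(tiny_literature_index(2)))
  expect_identical(out$monitoring$code, 0L)
  entry <- out$signals[[1]]
  expect_identical(entry$score, 0.5)
  expect_length(entry$annotations, 2)
  expect_true(all(vapply(entry$annotations, `[[`, character(1), "kind") ==
                    "pubmed"))

  out0 <- run_literature_provider(doc, manual_world(tiny_literature_index(0)))
  expect_identical(out0$signals[[1]]$score, 0)
  expect_length(out0$signals[[1]]$annotations, 0)
})

test_that("adding an irrelevant publication never changes a score", {
  doc <- exchange_input(list(tiny_pair()))
  for (n in 0:4) {
    a <- run_literature_provider(doc,
      manual_world(tiny_literature_index(n, n_background = 0)))
    b <- run_literature_provider(doc,
      manual_world(tiny_literature_index(n, n_background = 7)))
    expect_identical(a$signals[[1]]$score, b$signals[[1]]$score)
  }
})

test_that("a missing literature index yields monitoring code 41", {
  out <- run_literature_provider(exchange_input(list(tiny_pair())),
                                 manual_world(literature = NULL))
  expect_identical(out$monitoring$code, 41L)
  expect_length(out$signals, 0)
})

test_that("an unresolvable term scores 0 with a note and flips status to 12", {
  pair2 <- make_pair(drug_ref("B01AC06"), event_ref("EV01"))
  doc <- exchange_input(list(tiny_pair(), pair2))
  out <- run_literature_provider(doc, manual_world(tiny_literature_index(3)))
  expect_identical(out$monitoring$code, 12L)
  expect_length(out$signals, 2)
  expect_identical(out$signals[[1]]$score, 1)
  expect_identical(out$signals[[2]]$score, 0)
  expect_identical(out$signals[[2]]$annotations[[1]]$value, "unmapped-term")
})
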