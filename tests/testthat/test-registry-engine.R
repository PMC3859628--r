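test_that("registration enforces unique provider ids and lists metadata", {
  reg <- provider_registry()
  desc <- provider_descriptor("literature", "Literature", "1.0",
                              function(doc, world) doc)
  register_provider(reg, desc)
  expect_identical(nrow(list_providers(reg)), 1L)
  expect_error(register_provider(reg, desc),
               class = "adrsub_validation_error")
})

test_that("the bundled registry lists the four providers", {
  lp <- list_providers(default_registry())
  expect_identical(nrow(lp), 4L)
  expect_setequal(lp$provider_id,
                  c("literature", "cooccurrence", "targets", "combination"))
  expect_identical(lp$kind[lp$provider_id == "combination"], "combiner")
})

test_that("a drug study pairs the drug with every vocabulary event in order", {
  study <- create_drug_study("A10BA02")
  expect_length(study, 11)
  expect_identical(vapply(study, function(p) p$event$event_code,
                          character(1)),
                   default_event_vocabulary()$event_code)
  expect_true(all(vapply(study, function(p) p$drug$atc_code,
                         character(1)) == "A10BA02"))

  one <- create_drug_study("A10BA02",
                           data.frame(event_code = "EV01", name = "x"))
  expect_length(one, 1)
  expect_error(create_drug_study("A10BA02",
                                 data.frame(event_code = character(0),
                                            name = character(0))),
               class = "adrsub_validation_error")
  expect_error(create_drug_study("bad atc"),
               class = "adrsub_validation_error")
})

test_that("execute runs providers and validates preconditions", {
  w <- manual_world(literature = tiny_literature_index(3))
  pairs <- list(tiny_pair())
  h <- execute(pairs, "literature", w)
  expect_identical(h$state, "done")
  expect_identical(h$results$literature$status$code, 0L)
  expect_identical(h$results$literature$scored_pairs[[1]]$score, 1)

  expect_error(execute(list(), "literature", w),
               class = "adrsub_validation_error")
  expect_error(execute(pairs, character(0), w),
               class = "adrsub_validation_error")
  expect_error(execute(pairs, "nope", w),
               class = "adrsub_not_found_error")
})

test_that("one provider's failure does not abort the run and is status-coded", {
  w <- manual_world(literature = tiny_literature_index(1), corpus = NULL)
  h <- execute(list(tiny_pair()), c("literature", "cooccurrence"), w)
  expect_identical(h$state, "done")
  expect_identical(h$results$literature$status$code, 0L)
  expect_identical(h$results$cooccurrence$status$code, 41L)
  expect_setequal(names(h$results), c("literature", "cooccurrence"))

  # a provider that throws is mapped to code 40, not propagated
  reg <- provider_registry()
  register_provider(reg, provider_descriptor(
    "boom", "Crashing provider", "0.1",
    function(doc, world) stop("kaput")))
  register_provider(reg, provider_descriptor(
    "literature", "Literature", "1.0",
    function(doc, world) run_literature_provider(doc, world)))
  h2 <- execute(list(tiny_pair()), c("boom", "literature"), w,
                registry = reg)
  expect_identical(h2$results$boom$status$code, 40L)
  expect_identical(h2$results$literature$status$code, 0L)
})

test_that("providers work on isolated copies of the input", {
  w <- manual_world(literature = tiny_literature_index(1))
  mutator_saw <- new.env()
  reg <- provider_registry()
  register_provider(reg, provider_descriptor(
    "mutator", "Mutating provider", "0.1",
    function(doc, world) {
      doc$signals[[1]]$pair$drug$atc_code <- "Z99ZZ99"  # local copy only
      exchange_output("mutator", status_code(0L),
                      lapply(doc$signals, function(e)
                        list(pair = e$pair, score = 0, annotations = list())))
    }))
  register_provider(reg, provider_descriptor(
    "observer", "Observing provider", "0.1",
    function(doc, world) {
      mutator_saw$atc <- doc$signals[[1]]$pair$drug$atc_code
      exchange_output("observer", status_code(0L),
                      lapply(doc$signals, function(e)
                        list(pair = e$pair, score = 1, annotations = list())))
    }))
  h <- execute(list(tiny_pair()), c("mutator", "observer"), w,
               registry = reg)
  expect_identical(mutator_saw$atc, "A10BA02")
  # mutator returned different pairs than the input: flagged, not silent
  expect_identical(h$results$mutator$status$code, 40L)
  expect_identical(h$results$observer$status$code, 0L)
})

test_that("runs are deterministic given fixed world, dataset and providers", {
  w <- generate_world(world_config(seed = 3, n_drugs = 2, n_events = 3,
                                   n_planted = 2))
  wp <- world_pairs(w)
  ids <- c("literature", "cooccurrence", "targets", "combination")
  h1 <- execute(wp$pairs, ids, w)
  h2 <- execute(wp$pairs, ids, w)
  expect_equal(h1$results, h2$results)
  expect_equal(h1$verdicts, h2$verdicts)
})

test_that("store and load round-trip a finished run idempotently", {
  w <- manual_world(literature = tiny_literature_index(2))
  h <- execute(list(tiny_pair()), c("literature", "combination"), w)
  store <- withr::local_tempdir()
  store_results(h, store)
  store_results(h, store)  # idempotent
  expect_length(list.dirs(store, recursive = FALSE), 1)
  rec <- load_results(store, h$run_id)
  expect_equal(rec$results, h$results)
  expect_identical(rec$verdicts[[1]]$tier, h$verdicts[[1]]$tier)
  expect_equal(rec$verdicts[[1]]$belief, h$verdicts[[1]]$belief)
  expect_error(load_results(store, "run-does-not-exist"),
               class = "adrsub_not_found_error")

  h$state <- "running"  # not done any more
  expect_error(store_results(h, store), class = "adrsub_state_error")
})

test_that("run state can only move forward", {
  w <- manual_world(literature = tiny_literature_index(1))
  h <- execute(list(tiny_pair()), "literature", w)
  expect_error(adrsub:::set_handle_state(h, "pending"),
               class = "adrsub_state_error")
})

test_that("run_summary tabulates scores, flags and verdicts per pair", {
  w <- generate_world(world_config(seed = 5, n_drugs = 2, n_events = 3,
                                   n_planted = 1))
  wp <- world_pairs(w)
  h <- execute(wp$pairs, c("literature", "cooccurrence", "targets",
                           "combination"), w)
  s <- run_summary(h)
  expect_identical(nrow(s), length(wp$pairs))
  expect_true(all(c("score_literature", "flag_literature", "belief",
                    "tier") %in% names(s)))
  expect_true(all(s$tier %in% c("L", "M", "H")))
  expect_true(all(s$belief <= s$plausibility + 1e-12))
  expect_true(all((s$score_literature >= 0.5) == (s$flag_literature == "Y")))
})

test_that("configuration files round into substantiation_config", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("alpha: 0.01",
               "mass_mode: two_sided",
               "evidence_cutoff: 0.6",
               "tier_thresholds:",
               "  moderate: 0.2",
               "  high: 0.8",
               "weights:",
               "  literature: 0.9"), path)
  cfg <- read_substantiation_config(path)
  expect_equal(cfg$alpha, 0.01)
  expect_identical(cfg$combination$mode, "two_sided")
  expect_equal(cfg$combination$tier_thresholds, c(M = 0.2, H = 0.8))
  expect_equal(cfg$combination$weights, c(literature = 0.9))
})
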