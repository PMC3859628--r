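# Shared fixture builders. Everything is constructed in code; no stored
# binary fixtures.

# A minimal literature index where `n_matching` publications support the
# pair (A10BA02, EV01) via the "adverse effects" qualifier, plus some
# irrelevant background publications.
tiny_literature_index <- function(n_matching, n_background = 2) {
  records <- list()
  for (i in seq_len(n_matching)) {
    records[[sprintf("2000%04d", i)]] <- data.frame(
      descriptor = c("D_A10BA02", "E_EV01", "X_001"),
      qualifier = c("adverse effects", NA, NA),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_background)) {
    records[[sprintf("9000%04d", i)]] <- data.frame(
      descriptor = c("X_002", "X_003"),
      qualifier = c("adverse effects", NA),
      stringsAsFactors = FALSE)
  }
  literature_index(records,
                   drug_map = c(A10BA02 = "D_A10BA02"),
                   event_map = c(EV01 = "E_EV01"))
}

tiny_pair <- function() {
  make_pair(drug_ref("A10BA02", "metformin"),
            event_ref("EV01", "acute myocardial infarction"))
}

# A world with only the supplied components; unspecified knowledge
# sources are absent (NULL), which providers must report as code 41.
manual_world <- function(literature = NULL, corpus = NULL,
                         drug_profiles = NULL, event_profiles = NULL,
                         pathway_map = NULL) {
  structure(list(
    drugs = data.frame(atc_code = "A10BA02", name = "metformin",
                       stringsAsFactors = FALSE),
    events = data.frame(event_code = "EV01",
                        name = "acute myocardial infarction",
                        stringsAsFactors = FALSE),
    literature = literature, corpus = corpus,
    drug_profiles = drug_profiles, event_profiles = event_profiles,
    pathway_map = pathway_map,
    planted = data.frame(atc_code = character(0),
                         event_code = character(0),
                         stringsAsFactors = FALSE),
    config = NULL), class = "knowledge_world")
}

# Single-resource corpus index realizing a chosen 2x2 table for the
# tiny pair.
tiny_corpus <- function(n11, n_d, n_e, N, resource = "medline") {
  corpus_counts(resource, N,
                drug_counts = c(A10BA02 = n_d),
                event_counts = c(EV01 = n_e),
                joint = data.frame(drug = "A10BA02", event = "EV01",
                                   count = n11, stringsAsFactors = FALSE))
}

# Random canonical exchange document for round-trip property tests.
# Scores and stats are quantized to 6 fractional digits (the canonical
# serialization granularity).
random_document <- function(direction = c("input", "output")) {
  direction <- match.arg(direction)
  q6 <- function(n) (sample.int(1000001L, n, replace = TRUE) - 1L) / 1e6
  n <- sample(0:6, 1)
  codes <- sprintf("%s%02d%s%s%02d",
                   sample(LETTERS, 12, replace = TRUE),
                   sample(0:99, 12, replace = TRUE),
                   sample(LETTERS, 12, replace = TRUE),
                   sample(LETTERS, 12, replace = TRUE),
                   sample(0:99, 12, replace = TRUE))
  keys <- expand.grid(atc = unique(codes)[1:3],
                      ev = sprintf("EV%02d", 1:4),
                      stringsAsFactors = FALSE)
  keys <- keys[sample.int(nrow(keys), n), , drop = FALSE]
  entries <- lapply(seq_len(nrow(keys)), function(i) {
    stats <- NULL
    if (stats::runif(1) < 0.5) {
      stats <- as.list(q6(sample(1:2, 1)))
      names(stats) <- paste0("s", seq_along(stats))
    }
    pair <- make_pair(drug_ref(keys$atc[i],
                               if (stats::runif(1) < 0.5) "a drug & <name>"
                               else NA_character_),
                      event_ref(keys$ev[i], sprintf("event \"%d\"", i)),
                      mining_stats = stats)
    anns <- if (direction == "output" && stats::runif(1) < 0.5) {
      lapply(seq_len(sample(1:3, 1)), function(j)
        annotation(sample(c("pubmed", "uniprot", "resource", "other"), 1),
                   sprintf("id-%d", j),
                   if (stats::runif(1) < 0.5) "label <x>" else NA_character_))
    } else list()
    list(pair = pair,
         score = if (direction == "output") q6(1) else NULL,
         annotations = anns)
  })
  if (direction == "input") {
    exchange_input(lapply(entries, `[[`, "pair"))
  } else {
    exchange_output(sample(c("literature", "cooccurrence", "targets"), 1),
                    status_code(sample(c(0L, 41L), 1)),
                    if (stats::runif(1) < 0.9) entries else list())
  }
}
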