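# Provider registry and execution engine. Providers are in-process
# callables with the contract entry(input exchange_document, world) ->
# output exchange_document; the engine mediates every call through
# serialized documents so each provider works on an isolated copy, mirrors
# per-provider failures into nonzero monitoring codes without aborting the
# run, and collects results under a run handle that can be persisted.

#' Create an empty provider registry
#'
#' @return An object of class `provider_registry`.
#' @export
provider_registry <- function() {
  structure(new.env(parent = emptyenv()), class = "provider_registry")
}

#' Describe a knowledge provider
#'
#' @param provider_id Unique identifier.
#' @param name Human-readable name.
#' @param version Version string.
#' @param entry Function `(doc, world) -> doc` for scoring providers;
#'   ignored for the combiner.
#' @param kind `"scoring"` or `"combiner"`.
#' @return An object of class `provider_descriptor`.
#' @export
provider_descriptor <- function(provider_id, name, version, entry,
                                kind = c("scoring", "combiner")) {
  kind <- match.arg(kind)
  if (!is_string(provider_id) || !nzchar(provider_id)) {
    abort_validation("provider_id must be a non-empty string")
  }
  if (kind == "scoring" && !is.function(entry)) {
    abort_validation("a scoring provider needs an entry function")
  }
  structure(list(provider_id = provider_id, name = name, version = version,
                 entry = entry, kind = kind),
            class = "provider_descriptor")
}

#' Register a provider
#'
#' @param registry A [provider_registry()].
#' @param desc A [provider_descriptor()].
#' @return The registry, invisibly.
#' @export
register_provider <- function(registry, desc) {
  if (!inherits(desc, "provider_descriptor")) {
    abort_validation("desc must be a provider_descriptor")
  }
  if (exists(desc$provider_id, envir = registry, inherits = FALSE)) {
    abort_validation(sprintf("provider %s already registered",
                             sQuote(desc$provider_id)))
  }
  assign(desc$provider_id, desc, envir = registry)
  invisible(registry)
}

#' List registered providers
#'
#' @param registry A [provider_registry()].
#' @return Data frame with columns `provider_id`, `name`, `version`, `kind`.
#' @export
list_providers <- function(registry) {
  ids <- sort(ls(registry))
  data.frame(
    provider_id = ids,
    name = vapply(ids, function(i) get(i, envir = registry)$name, character(1)),
    version = vapply(ids, function(i) get(i, envir = registry)$version,
                     character(1)),
    kind = vapply(ids, function(i) get(i, envir = registry)$kind, character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Registry pre-loaded with the four bundled providers
#'
#' Three scoring providers (literature, co-occurrence, target profiles)
#' plus the evidence combiner.
#'
#' @param config A [substantiation_config()] supplying provider options.
#' @return A [provider_registry()] listing 4 providers.
#' @export
default_registry <- function(config = substantiation_config()) {
  reg <- provider_registry()
  register_provider(reg, provider_descriptor(
    "literature", "Literature analysis (MeSH subheading rule)", "1.0",
    function(doc, world)
      run_literature_provider(doc, world, rule = config$match_rule)))
  register_provider(reg, provider_descriptor(
    "cooccurrence", "Co-occurrence chi-square filter", "1.0",
    function(doc, world)
      run_cooccurrence_provider(doc, world, alpha = config$alpha,
                                correction = config$yates_correction)))
  register_provider(reg, provider_descriptor(
    "targets", "Target-profile signal substantiation", "1.0",
    function(doc, world)
      run_target_provider(doc, world, mode = config$target_mode,
                          k = config$target_k)))
  register_provider(reg, provider_descriptor(
    "combination", "Dempster-Shafer evidence combination", "1.0",
    entry = NULL, kind = "combiner"))
  reg
}

.run_counter <- new.env(parent = emptyenv())

next_run_id <- function() {
  n <- (get0("n", envir = .run_counter, ifnotfound = 0L)) + 1L
  assign("n", n, envir = .run_counter)
  sprintf("run-%d-%04d", Sys.getpid(), n)
}

set_handle_state <- function(handle, state) {
  order <- c(pending = 1L, running = 2L, done = 3L, failed = 3L)
  if (order[[state]] < order[[handle$state]]) {
    abort_state(sprintf("cannot move run state backwards (%s -> %s)",
                        handle$state, state))
  }
  assign("state", state, envir = handle)
  invisible(handle)
}

output_doc_to_result <- function(doc) {
  provider_result(doc$provider_id, doc$monitoring,
                  scored_pairs = lapply(doc$signals, function(e)
                    list(pair = e$pair, score = e$score,
                         annotations = e$annotations)))
}

#' Execute providers on a dataset
#'
#' Serializes the dataset to a canonical input document, feeds an
#' independently parsed copy to each requested scoring provider, and
#' collects their output documents. A provider that throws, or that
#' returns an invalid document, is recorded with monitoring code 40 and
#' does not abort the run. When `"combination"` is among the requested
#' providers, the combiner is run last over the scoring results, yielding
#' one [combine_all()] verdict per pair (providers with nonzero status are
#' excluded from the fold).
#'
#' @param pairs A [pair_dataset()] or list of pairs (non-empty).
#' @param provider_ids Character vector of registered provider ids.
#' @param world A `knowledge_world`.
#' @param registry A [provider_registry()]; defaults to the bundled four.
#' @param config A [substantiation_config()].
#' @return A `run_handle` (environment) with fields `run_id`, `state`,
#'   `results` (provider id to [provider_result()]), `verdicts` (named by
#'   pair key when the combiner ran), `input_xml`, `output_xml`.
#' @export
execute <- function(pairs, provider_ids, world,
                    registry = default_registry(config),
                    config = substantiation_config()) {
  if (!length(pairs)) abort_validation("dataset must be non-empty")
  if (!length(provider_ids)) abort_validation("at least one provider required")
  unknown <- provider_ids[!vapply(provider_ids, exists, logical(1),
                                  envir = registry, inherits = FALSE)]
  if (length(unknown)) {
    abort_not_found(sprintf("unknown provider id(s): %s",
                            paste(sQuote(unknown), collapse = ", ")))
  }
  if (anyDuplicated(provider_ids)) {
    abort_validation("provider_ids must be unique")
  }
  descs <- lapply(provider_ids, get, envir = registry)
  names(descs) <- provider_ids
  combine <- vapply(descs, function(d) d$kind == "combiner", logical(1))

  input_doc <- exchange_input(pairs)
  input_xml <- format_document(input_doc)

  handle <- new.env(parent = emptyenv())
  class(handle) <- "run_handle"
  handle$run_id <- next_run_id()
  handle$state <- "pending"
  handle$provider_ids <- provider_ids
  handle$input_xml <- input_xml
  set_handle_state(handle, "running")

  results <- list()
  output_xml <- list()
  for (desc in descs[!combine]) {
    out_doc <- tryCatch({
      doc_copy <- read_document(input_xml)   # provider isolation
      out <- desc$entry(doc_copy, world)
      # re-serialize through the dialect so invalid provider output is
      # caught here, not downstream
      read_document(format_document(out))
    }, error = function(e) {
      exchange_output(desc$provider_id, status_code(40L, paste0(
        "internal provider error: ", conditionMessage(e))))
    })
    if (out_doc$monitoring$code == 0L &&
        !same_pair_set(out_doc$signals, input_doc$signals)) {
      out_doc <- exchange_output(desc$provider_id, status_code(40L,
        "internal provider error: output pairs do not match input pairs"))
    }
    results[[desc$provider_id]] <- output_doc_to_result(out_doc)
    output_xml[[desc$provider_id]] <- format_document(out_doc)
  }
  handle$results <- results
  handle$output_xml <- output_xml

  if (any(combine)) {
    handle$verdicts <- combine_run_results(results, input_doc, config)
  }
  set_handle_state(handle, "done")
  handle
}

same_pair_set <- function(out_signals, in_signals) {
  setequal(vapply(out_signals, function(e) pair_key(e$pair), character(1)),
           vapply(in_signals, function(e) pair_key(e$pair), character(1))) &&
    length(out_signals) == length(in_signals)
}

combine_run_results <- function(results, input_doc, config) {
  usable <- Filter(function(r) r$status$code == 0L, results)
  verdicts <- list()
  for (entry in input_doc$signals) {
    key <- pair_key(entry$pair)
    scores <- vapply(usable, function(r) {
      idx <- which(vapply(r$scored_pairs, function(sp)
        pair_key(sp$pair), character(1)) == key)
      r$scored_pairs[[idx[1]]]$score
    }, numeric(1))
    verdicts[[gsub("\x1f", "/", key)]] <-
      if (length(scores)) {
        tryCatch(combine_all(scores, config$combination),
                 adrsub_conflict_error = function(e) e)
      } else NULL
  }
  verdicts
}

#' @export
print.run_handle <- function(x, ...) {
  cat(sprintf("<run %s> state %s, %d provider result(s)%s\n", x$run_id,
              x$state, length(x$results),
              if (!is.null(x$verdicts)) sprintf(", %d verdict(s)",
                                                length(x$verdicts)) else ""))
  invisible(x)
}

#' Create a drug study: one pair per vocabulary event
#'
#' Combines a single drug with every event in the vocabulary, in
#' vocabulary order. With the bundled default vocabulary this yields the
#' 11-event study panel.
#'
#' @param drug A [drug_ref()] or ATC code string.
#' @param vocabulary Event vocabulary: a data frame with `event_code`,
#'   `name` or a list of [event_ref()]; defaults to the bundled 11 events.
#' @return A [pair_dataset()].
#' @export
create_drug_study <- function(drug, vocabulary = default_event_vocabulary()) {
  if (!inherits(drug, "drug_ref")) drug <- drug_ref(drug)
  events <- vocabulary_to_events(vocabulary)
  if (!length(events)) abort_validation("vocabulary must be non-empty")
  pair_dataset(lapply(events, function(e) make_pair(drug, e)))
}

#' Persist a finished run
#'
#' Writes, under `store_path/<run_id>/`, the canonical input document, one
#' output document per provider, and a JSON manifest (statuses, verdicts).
#' Storing the same run twice overwrites the record in place (idempotent).
#'
#' @param handle A done `run_handle`.
#' @param store_path Store directory (created if needed).
#' @return The run directory path, invisibly.
#' @export
store_results <- function(handle, store_path) {
  if (!inherits(handle, "run_handle") || handle$state != "done") {
    abort_state("only a run in state 'done' can be stored")
  }
  run_dir <- file.path(store_path, handle$run_id)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  writeBin(charToRaw(handle$input_xml), file.path(run_dir, "input.xml"))
  for (id in names(handle$output_xml)) {
    writeBin(charToRaw(handle$output_xml[[id]]),
             file.path(run_dir, paste0("output-", id, ".xml")))
  }
  manifest <- list(
    run_id = handle$run_id,
    provider_ids = as.list(handle$provider_ids),
    statuses = lapply(handle$results, function(r)
      list(code = r$status$code, message = r$status$message)),
    verdicts = verdicts_to_json(handle$verdicts))
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(run_dir)
}

verdicts_to_json <- function(verdicts) {
  if (is.null(verdicts)) return(NULL)
  lapply(verdicts, function(v) {
    if (is.null(v)) return(NULL)
    if (inherits(v, "adrsub_conflict_error")) {
      return(list(error = conditionMessage(v)))
    }
    list(belief = v$belief, plausibility = v$plausibility, tier = v$tier,
         per_provider_flags = as.list(v$per_provider_flags))
  })
}

#' Load a stored run
#'
#' @param store_path Store directory.
#' @param run_id Run identifier.
#' @return List with `run_id`, `results` (equal in structure to the
#'   handle's results map), `verdicts`, `input` (the input document).
#' @export
load_results <- function(store_path, run_id) {
  run_dir <- file.path(store_path, run_id)
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort_not_found(sprintf("no stored run %s under %s", sQuote(run_id),
                            store_path))
  }
  manifest <- jsonlite::read_json(manifest_path)
  results <- list()
  for (id in names(manifest$statuses)) {
    doc <- read_document(file.path(run_dir, paste0("output-", id, ".xml")))
    results[[id]] <- output_doc_to_result(doc)
  }
  verdicts <- lapply(manifest$verdicts, function(v) {
    if (is.null(v) || !is.null(v$error)) return(v)
    list(belief = as.numeric(v$belief),
         plausibility = as.numeric(v$plausibility), tier = v$tier,
         per_provider_flags = unlist(v$per_provider_flags))
  })
  list(run_id = manifest$run_id, results = results,
       verdicts = if (length(verdicts)) verdicts else NULL,
       input = read_document(file.path(run_dir, "input.xml")))
}

#' Summarize a run as a data frame
#'
#' One row per pair with each provider's score and Y/N flag plus, when the
#' combiner ran, belief / plausibility / tier.
#'
#' @param handle A done `run_handle`.
#' @param config A [substantiation_config()] (for the evidence cutoff).
#' @return A data frame.
#' @export
run_summary <- function(handle, config = substantiation_config()) {
  if (!inherits(handle, "run_handle") || handle$state != "done") {
    abort_state("run is not done")
  }
  input <- read_document(handle$input_xml)
  keys <- vapply(input$signals, function(e) pair_key(e$pair), character(1))
  df <- data.frame(
    atc_code = vapply(input$signals, function(e) e$pair$drug$atc_code,
                      character(1)),
    event_code = vapply(input$signals, function(e) e$pair$event$event_code,
                        character(1)),
    stringsAsFactors = FALSE)
  for (id in names(handle$results)) {
    r <- handle$results[[id]]
    col <- rep(NA_real_, length(keys))
    if (r$status$code %in% c(0L, 12L)) {
      rkeys <- vapply(r$scored_pairs, function(sp) pair_key(sp$pair),
                      character(1))
      col <- vapply(keys, function(k) {
        i <- match(k, rkeys)
        if (is.na(i)) NA_real_ else r$scored_pairs[[i]]$score
      }, numeric(1))
    }
    df[[paste0("score_", id)]] <- col
    df[[paste0("flag_", id)]] <- ifelse(is.na(col), NA_character_,
      ifelse(col >= config$combination$evidence_cutoff, "Y", "N"))
  }
  if (!is.null(handle$verdicts)) {
    vkeys <- gsub("\x1f", "/", keys)
    pick <- function(field, default) vapply(vkeys, function(k) {
      v <- handle$verdicts[[k]]
      if (is.null(v) || inherits(v, "adrsub_conflict_error")) default
      else v[[field]]
    }, default)
    df$belief <- pick("belief", NA_real_)
    df$plausibility <- pick("plausibility", NA_real_)
    df$tier <- pick("tier", NA_character_)
  }
  rownames(df) <- NULL
  df
}
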