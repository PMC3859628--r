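# Literature-analysis knowledge provider. Counts publications whose
# MeSH-style annotations support a drug-event pair under the subheading
# rule -- the drug descriptor qualified "adverse effects", or the event
# descriptor qualified "chemically induced" -- and maps the count to the
# stepped 0 / 0.5 / 1 score.

QUALIFIER_ADVERSE_EFFECTS <- "adverse effects"
QUALIFIER_CHEMICALLY_INDUCED <- "chemically induced"

#' Literature annotation index
#'
#' An offline stand-in for an annotated literature corpus: one record per
#' publication listing (descriptor, qualifier) annotations, plus the
#' vocabulary maps resolving drugs and events to descriptors and the
#' optional pharmacological-action classes used to broaden drug matching.
#'
#' @param records Named list, publication id to data frame with columns
#'   `descriptor`, `qualifier` (`NA` for unqualified annotations).
#' @param drug_map Named character vector, ATC code to descriptor.
#' @param event_map Named character vector, event code to descriptor.
#' @param pharm_actions Named list, descriptor to character vector of
#'   action-class descriptors.
#' @return An object of class `literature_index`.
#' @export
literature_index <- function(records = list(), drug_map = character(0),
                             event_map = character(0),
                             pharm_actions = list()) {
  if (length(records) &&
      (is.null(names(records)) || anyDuplicated(names(records)))) {
    abort_validation("publication ids must be unique and named")
  }
  for (rec in records) {
    if (!is.data.frame(rec) ||
        !all(c("descriptor", "qualifier") %in% names(rec))) {
      abort_validation("each record needs columns descriptor, qualifier")
    }
  }
  structure(list(records = records,
                 drug_map = drug_map, event_map = event_map,
                 pharm_actions = pharm_actions),
            class = "literature_index")
}

#' Literature matching rule
#'
#' `mode = "either"` (the default) counts a publication when the drug
#' descriptor appears qualified "adverse effects" alongside the event
#' descriptor, or the event descriptor appears qualified "chemically
#' induced" alongside the drug descriptor. `mode = "both"` requires both
#' qualified matches in the same publication. When
#' `use_pharmacological_action` is on, the drug's descriptor set is
#' expanded with its action-class descriptors before matching.
#'
#' @param mode `"either"` or `"both"`.
#' @param use_pharmacological_action Logical.
#' @return An object of class `match_rule`.
#' @export
match_rule <- function(mode = c("either", "both"),
                       use_pharmacological_action = FALSE) {
  mode <- match.arg(mode)
  structure(list(mode = mode,
                 use_pharmacological_action = isTRUE(use_pharmacological_action)),
            class = "match_rule")
}

resolve_descriptor <- function(map, key, what) {
  if (!length(map) || is.na(match(key, names(map)))) {
    abort_mapping(sprintf("no descriptor mapping for %s %s", what, sQuote(key)))
  }
  unname(map[[key]])
}

#' Count publications supporting a drug-event pair
#'
#' Scans every publication in the index and applies the subheading rule
#' (see [match_rule()]).
#'
#' @param pair A [make_pair()] object.
#' @param index A [literature_index()].
#' @param rule A [match_rule()].
#' @return List with `n` (integer count) and `publication_ids` (sorted).
#' @export
count_supporting_publications <- function(pair, index,
                                          rule = match_rule()) {
  drug_desc <- resolve_descriptor(index$drug_map, pair$drug$atc_code, "drug")
  event_desc <- resolve_descriptor(index$event_map, pair$event$event_code,
                                   "event")
  drug_set <- drug_desc
  if (rule$use_pharmacological_action) {
    drug_set <- unique(c(drug_set, index$pharm_actions[[drug_desc]]))
  }
  hits <- vapply(index$records, function(rec) {
    in_drug <- rec$descriptor %in% drug_set
    is_event <- rec$descriptor == event_desc
    ae <- any(in_drug & !is.na(rec$qualifier) &
                rec$qualifier == QUALIFIER_ADVERSE_EFFECTS)
    ci <- any(is_event & !is.na(rec$qualifier) &
                rec$qualifier == QUALIFIER_CHEMICALLY_INDUCED)
    if (rule$mode == "both") {
      ae && ci
    } else {
      (ae && any(is_event)) || (ci && any(in_drug))
    }
  }, logical(1))
  ids <- sort(names(index$records)[hits])
  list(n = length(ids), publication_ids = ids)
}

#' Map a supporting-publication count to the literature score
#'
#' The stepped rule: no publications scores 0; one or two publications
#' score 0.5; three or more score 1.
#'
#' @param n Non-negative publication count.
#' @return A [score()].
#' @examples
#' sapply(0:4, score_from_count)
#' @export
score_from_count <- function(n) {
  if (!is_count(n)) abort_validation("publication count must be a non-negative integer")
  score(if (n == 0) 0 else if (n < 3) 0.5 else 1)
}

#' Run the literature provider on an exchange document
#'
#' Scores every signal via the publication count and annotates positive
#' scores with one `pubmed` link per supporting publication. A pair whose
#' drug or event cannot be resolved to a descriptor scores 0 with an
#' `other`-kind "unmapped-term" note, and the document-level status becomes
#' 12 (mapping miss) while the run continues. A missing literature index
#' yields monitoring code 41 with no signals.
#'
#' @param doc Input `exchange_document`.
#' @param world A `knowledge_world` (see [generate_world()]).
#' @param rule A [match_rule()].
#' @return Output `exchange_document` for provider `"literature"`.
#' @export
run_literature_provider <- function(doc, world, rule = match_rule()) {
  index <- world$literature
  if (is.null(index) || !inherits(index, "literature_index")) {
    return(exchange_output("literature", status_code(41L)))
  }
  any_miss <- FALSE
  signals <- lapply(doc$signals, function(entry) {
    res <- tryCatch(
      count_supporting_publications(entry$pair, index, rule),
      adrsub_mapping_error = function(e) e)
    if (inherits(res, "adrsub_mapping_error")) {
      any_miss <<- TRUE
      return(list(pair = entry$pair, score = 0,
                  annotations = list(annotation("other", "unmapped-term",
                                                conditionMessage(res)))))
    }
    anns <- if (res$n > 0) {
      lapply(res$publication_ids, function(id) annotation("pubmed", id))
    } else list()
    list(pair = entry$pair,
         score = as.numeric(score_from_count(res$n)),
         annotations = anns)
  })
  exchange_output("literature",
                  if (any_miss) status_code(12L) else status_code(0L),
                  signals)
}
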