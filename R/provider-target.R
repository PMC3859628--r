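# Target-profile signal-substantiation provider. Intersects the drug's
# target-protein profile with the event's associated-protein profile and
# annotates the shared proteins plus every pathway reachable from them.

#' Intersect a drug-target and an event-target profile
#'
#' @param drug_profile,event_profile Character vectors of protein
#'   accessions (set semantics; duplicates ignored).
#' @return Sorted character vector of shared accessions.
#' @export
intersect_profiles <- function(drug_profile, event_profile) {
  sort(intersect(unique(as.character(drug_profile)),
                 unique(as.character(event_profile))))
}

#' Score a shared-protein set
#'
#' Binary mode (the default) scores 1 when the intersection is non-empty;
#' graded mode scores `min(1, |shared| / k)`.
#'
#' @param shared Character vector of shared accessions.
#' @param mode `"binary"` or `"graded"`.
#' @param k Saturation count for graded mode (score reaches 1 at `k`
#'   shared proteins); must be a positive integer.
#' @return A [score()].
#' @export
score_intersection <- function(shared, mode = c("binary", "graded"), k = 1) {
  mode <- match.arg(mode)
  n <- length(unique(shared))
  if (mode == "binary") return(score(as.numeric(n > 0)))
  if (!is_count(k) || k < 1) abort_config("graded mode requires integer k >= 1")
  score(min(1, n / k))
}

#' Run the target-profile provider on an exchange document
#'
#' Per pair: the shared-protein set is computed, scored per the configured
#' mode, and annotated with one `uniprot` annotation per shared protein
#' plus one `reactome` annotation per pathway reachable from any shared
#' protein (deduplicated, lexicographically sorted). A pair lacking a
#' profile on either side scores 0 with an `other`-kind "no-profile" note.
#' A missing profile store yields monitoring code 41. Without a pathway
#' map, shared proteins are still annotated and a "pathway-map-missing"
#' note is added.
#'
#' @param doc Input `exchange_document`.
#' @param world A `knowledge_world`.
#' @param mode,k Passed to [score_intersection()].
#' @return Output `exchange_document` for provider `"targets"`.
#' @export
run_target_provider <- function(doc, world, mode = c("binary", "graded"),
                                k = 1) {
  mode <- match.arg(mode)
  if (is.null(world$drug_profiles) || is.null(world$event_profiles)) {
    return(exchange_output("targets", status_code(41L)))
  }
  pathway_map <- world$pathway_map
  signals <- lapply(doc$signals, function(entry) {
    dp <- world$drug_profiles[[entry$pair$drug$atc_code]]
    ep <- world$event_profiles[[entry$pair$event$event_code]]
    if (is.null(dp) || is.null(ep)) {
      return(list(pair = entry$pair, score = 0,
                  annotations = list(annotation("other", "no-profile",
                    "no target profile for drug or event"))))
    }
    shared <- intersect_profiles(dp, ep)
    s <- as.numeric(score_intersection(shared, mode, k))
    anns <- lapply(shared, function(p) annotation("uniprot", p))
    if (length(shared)) {
      if (is.null(pathway_map)) {
        anns <- c(anns, list(annotation("other", "pathway-map-missing",
                                        "no pathway map in knowledge world")))
      } else {
        pathways <- sort(unique(unlist(lapply(shared, function(p)
          pathway_map[[p]]))))
        anns <- c(anns, lapply(pathways, function(pw)
          annotation("reactome", pw)))
      }
    }
    list(pair = entry$pair, score = s, annotations = anns)
  })
  exchange_output("targets", status_code(0L), signals)
}
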