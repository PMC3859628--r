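# Co-occurrence knowledge provider. For each indexed resource (Medline
# titles/abstracts, DailyMed product characteristics, DrugBank links in
# the original setting; here any named document-count index) it tests the
# 2x2 drug x event document-count table with a Pearson chi-square and
# scores 1 when a non-chance, enriched co-occurrence is found in at least
# one resource.

COOC_RESOURCES <- c("medline", "dailymed", "drugbank")

#' Document-count index for one resource
#'
#' Margin and joint document counts over a corpus of `N` documents.
#'
#' @param resource Resource name (e.g. `"medline"`).
#' @param N Total number of documents in the corpus.
#' @param drug_counts Named integer vector: documents mentioning each drug.
#' @param event_counts Named integer vector: documents mentioning each event.
#' @param joint Data frame with columns `drug`, `event`, `count`:
#'   documents mentioning both.
#' @return An object of class `corpus_counts`.
#' @export
corpus_counts <- function(resource, N, drug_counts, event_counts, joint) {
  if (!is_string(resource)) abort_validation("resource must be a string")
  if (!is_count(N) || N < 1) abort_validation("N must be a positive integer")
  if (!is.data.frame(joint) ||
      !all(c("drug", "event", "count") %in% names(joint))) {
    abort_validation("joint must have columns drug, event, count")
  }
  if (any(drug_counts < 0) || any(event_counts < 0) || any(joint$count < 0)) {
    abort_validation("counts must be non-negative")
  }
  if (any(drug_counts > N) || any(event_counts > N)) {
    abort_validation("margin counts cannot exceed N")
  }
  for (i in seq_len(nrow(joint))) {
    nd <- drug_counts[[joint$drug[i]]]
    ne <- event_counts[[joint$event[i]]]
    if (is.null(nd) || is.null(ne) || joint$count[i] > min(nd, ne)) {
      abort_validation(sprintf(
        "joint count for (%s, %s) exceeds its margins or lacks them",
        joint$drug[i], joint$event[i]))
    }
  }
  structure(list(resource = resource, N = as.integer(N),
                 drug_counts = drug_counts, event_counts = event_counts,
                 joint = joint),
            class = "corpus_counts")
}

#' Pearson chi-square test on a 2x2 co-occurrence table
#'
#' The table is reconstructed from the joint count `n11`, the margins
#' `n_d` (documents with the drug), `n_e` (documents with the event) and
#' the corpus size `N`: `n10 = n_d - n11`, `n01 = n_e - n11`,
#' `n00 = N - n_d - n_e + n11`. The statistic is the closed form
#' `N (n11 n00 - n10 n01)^2 / (r1 r0 c1 c0)`; with Yates' continuity
#' correction the absolute cross-product difference is reduced by `N/2`
#' (floored at zero) before squaring. The p-value uses the chi-square
#' distribution with 1 degree of freedom.
#'
#' @param n11 Joint document count.
#' @param n_d,n_e Drug and event margin counts.
#' @param N Corpus size.
#' @param correction Apply Yates' continuity correction?
#' @return An object of class `chi2_result` with fields `statistic`,
#'   `p_value` and `enriched` (`TRUE` when `n11` exceeds the expectation
#'   `n_d * n_e / N` under independence).
#' @examples
#' chi_square_2x2(20, 30, 30, 100)
#' @export
chi_square_2x2 <- function(n11, n_d, n_e, N, correction = FALSE) {
  for (v in list(n11, n_d, n_e, N)) {
    if (!is_count(v)) abort_validation("all counts must be non-negative integers")
  }
  # double arithmetic: cross-products overflow 32-bit integers
  n11 <- as.numeric(n11); n_d <- as.numeric(n_d)
  n_e <- as.numeric(n_e); N <- as.numeric(N)
  n10 <- n_d - n11
  n01 <- n_e - n11
  n00 <- N - n_d - n_e + n11
  if (n10 < 0 || n01 < 0 || n00 < 0) {
    abort_validation("inconsistent table: joint count exceeds a margin or N")
  }
  r1 <- n_d; r0 <- N - n_d; c1 <- n_e; c0 <- N - n_e
  if (r1 == 0 || r0 == 0 || c1 == 0 || c0 == 0) {
    abort_degenerate("degenerate 2x2 table: a margin is zero")
  }
  diff <- abs(n11 * n00 - n10 * n01)
  if (correction) diff <- max(0, diff - N / 2)
  statistic <- N * diff^2 / (r1 * r0 * c1 * c0)
  structure(list(statistic = statistic,
                 p_value = stats::pchisq(statistic, df = 1,
                                         lower.tail = FALSE),
                 enriched = n11 > n_d * n_e / N),
            class = "chi2_result")
}

#' @export
print.chi2_result <- function(x, ...) {
  cat(sprintf("<chi2 2x2> X^2 = %.4f, p = %.4g, %s\n", x$statistic,
              x$p_value, if (x$enriched) "enriched" else "not enriched"))
  invisible(x)
}

#' Run the co-occurrence provider on an exchange document
#'
#' Each pair is tested in every resource where both terms are indexed.
#' An interaction is "found" when the chi-square test is significant at
#' `alpha` AND the joint count exceeds its independence expectation
#' (enrichment: a significantly depleted co-occurrence is not evidence for
#' the association). Any resource with a found interaction scores the pair
#' 1 and adds one `resource` annotation; otherwise the pair scores 0, with
#' an `other`-kind "not-indexed" note when no resource indexes both terms.
#' No usable resource index at all yields monitoring code 41.
#'
#' @param doc Input `exchange_document`.
#' @param world A `knowledge_world`.
#' @param alpha Significance level in (0,1); default 0.05.
#' @param correction Apply Yates' correction to each test?
#' @return Output `exchange_document` for provider `"cooccurrence"`.
#' @export
run_cooccurrence_provider <- function(doc, world, alpha = 0.05,
                                      correction = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    abort_config("alpha must lie strictly between 0 and 1")
  }
  corpus <- world$corpus
  if (is.null(corpus) || !length(corpus)) {
    return(exchange_output("cooccurrence", status_code(41L)))
  }
  signals <- lapply(doc$signals, function(entry) {
    atc <- entry$pair$drug$atc_code
    ev <- entry$pair$event$event_code
    significant <- character(0)
    indexed_anywhere <- FALSE
    for (cc in corpus) {
      n_d <- cc$drug_counts[atc]
      n_e <- cc$event_counts[ev]
      if (is.na(n_d) || is.na(n_e)) next
      indexed_anywhere <- TRUE
      j <- which(cc$joint$drug == atc & cc$joint$event == ev)
      n11 <- if (length(j)) cc$joint$count[j[1]] else 0L
      res <- tryCatch(
        chi_square_2x2(n11, unname(n_d), unname(n_e), cc$N, correction),
        adrsub_degenerate_table_error = function(e) NULL)
      if (!is.null(res) && res$p_value < alpha && res$enriched) {
        significant <- c(significant, cc$resource)
      }
    }
    if (length(significant)) {
      list(pair = entry$pair, score = 1,
           annotations = lapply(sort(significant), function(r)
             annotation("resource", r)))
    } else {
      anns <- if (!indexed_anywhere) {
        list(annotation("other", "not-indexed",
                        "pair not indexed in any resource"))
      } else list()
      list(pair = entry$pair, score = 0, annotations = anns)
    }
  })
  exchange_output("cooccurrence", status_code(0L), signals)
}
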