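#' Validate an ATC classification code
#'
#' Checks a string against the Anatomical Therapeutic Chemical layout. A full
#' substance-level code has 7 characters (letter, two digits, two letters,
#' two digits, e.g. `A10BA02`); the shorter prefixes at levels 1/2/3/4
#' (1, 3, 4 and 5 characters) are accepted as class-level codes, since a
#' drug study may target a whole therapeutic class.
#'
#' @param code Character vector of candidate codes.
#' @return Logical vector, `TRUE` where the code matches a valid ATC level.
#' @examples
#' validate_atc(c("A10BA02", "A10", "10ABA02"))
#' @export
validate_atc <- function(code) {
  if (!is.character(code)) return(rep(FALSE, length(code)))
  pattern <- paste0(
    "^([A-Z]|",              # level 1: anatomical main group
    "[A-Z][0-9]{2}|",        # level 2: therapeutic subgroup
    "[A-Z][0-9]{2}[A-Z]|",   # level 3: pharmacological subgroup
    "[A-Z][0-9]{2}[A-Z]{2}|",# level 4: chemical subgroup
    "[A-Z][0-9]{2}[A-Z]{2}[0-9]{2})$" # level 5: substance
  )
  !is.na(code) & grepl(pattern, code)
}

#' Drug reference
#'
#' A drug identified by its ATC code, optionally named. Codes shorter than
#' 7 characters are flagged as class-level.
#'
#' @param atc_code ATC code string (any valid ATC level).
#' @param name Optional drug name.
#' @return An object of class `drug_ref`.
#' @examples
#' drug_ref("A10BA02", "metformin")
#' @export
drug_ref <- function(atc_code, name = NA_character_) {
  if (!is_string(atc_code) || !validate_atc(atc_code)) {
    abort_validation(sprintf("invalid ATC code: %s",
                             if (is_string(atc_code)) sQuote(atc_code) else "<non-string>"))
  }
  if (!is.na(name) && !is_string(name)) {
    abort_validation("drug name must be a single string or NA")
  }
  structure(
    list(atc_code = atc_code, name = as.character(name),
         class_level = nchar(atc_code) < 7L),
    class = "drug_ref"
  )
}

#' Adverse-event reference
#'
#' An adverse event identified by a code in the active event vocabulary.
#' The vocabulary is project-supplied; the bundled default (see
#' [default_event_vocabulary()]) carries synthetic codes and names.
#'
#' @param event_code Non-empty event code string.
#' @param name Event name.
#' @return An object of class `event_ref`.
#' @export
event_ref <- function(event_code, name = NA_character_) {
  if (!is_string(event_code) || !nzchar(event_code)) {
    abort_validation("event code must be a non-empty string")
  }
  if (!is.na(name) && !is_string(name)) {
    abort_validation("event name must be a single string or NA")
  }
  structure(list(event_code = event_code, name = as.character(name)),
            class = "event_ref")
}

#' Drug-event pair
#'
#' The unit of pharmacovigilance evaluation: a coded drug paired with a
#' coded adverse event, optionally carrying researcher-imported mining
#' statistics which are passed through untouched by every provider.
#'
#' @param drug A [drug_ref()].
#' @param event An [event_ref()].
#' @param mining_stats Optional named list (or named numeric vector) of
#'   statistic name to numeric value.
#' @return An object of class `drug_event_pair`.
#' @examples
#' make_pair(drug_ref("A10BA02"), event_ref("EV01", "acute liver injury"),
#'           mining_stats = list(detection_score = 0.8))
#' @export
make_pair <- function(drug, event, mining_stats = NULL) {
  if (!inherits(drug, "drug_ref")) drug <- drug_ref(drug)
  if (!inherits(event, "event_ref")) event <- event_ref(event)
  if (!is.null(mining_stats)) {
    mining_stats <- as.list(mining_stats)
    if (length(mining_stats) &&
        (is.null(names(mining_stats)) || any(!nzchar(names(mining_stats))) ||
         !all(vapply(mining_stats, function(v)
           is.numeric(v) && length(v) == 1L && !is.na(v), logical(1))))) {
      abort_validation("mining_stats must be a named list of single numbers")
    }
    mining_stats <- lapply(mining_stats, as.numeric)
    if (!length(mining_stats)) mining_stats <- NULL
  }
  structure(list(drug = drug, event = event, mining_stats = mining_stats),
            class = "drug_event_pair")
}

pair_key <- function(pair) {
  paste(pair$drug$atc_code, pair$event$event_code, sep = "\x1f")
}

#' Assemble a dataset of drug-event pairs
#'
#' Enforces uniqueness of (ATC code, event code) within the dataset.
#'
#' @param pairs List of [make_pair()] objects.
#' @return The list, validated, with class `pair_dataset`.
#' @export
pair_dataset <- function(pairs) {
  if (!is.list(pairs) ||
      !all(vapply(pairs, inherits, logical(1), "drug_event_pair"))) {
    abort_validation("pairs must be a list of drug_event_pair objects")
  }
  keys <- vapply(pairs, pair_key, character(1))
  if (anyDuplicated(keys)) {
    dup <- keys[duplicated(keys)][1]
    abort_validation(sprintf("duplicate drug-event pair in dataset: %s",
                             gsub("\x1f", "/", dup)))
  }
  structure(pairs, class = "pair_dataset")
}

#' Score in the interchange scale
#'
#' Provider scores live in the closed unit interval; construction of any
#' value outside \[0,1\] is rejected.
#'
#' @param value A single number in \[0,1\].
#' @return A number of class `adr_score`.
#' @export
score <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 1) {
    abort_validation("score must be a single number in [0,1]")
  }
  structure(as.numeric(value), class = "adr_score")
}

ANNOTATION_KINDS <- c("pubmed", "uniprot", "smiles", "reactome", "resource",
                      "other")

#' Evidence annotation
#'
#' A typed link to supporting evidence: literature (PubMed ids), proteins
#' (UniProt accessions), chemical structures (SMILES), pathways (Reactome
#' ids), a knowledge resource name, or a free-form note (`other`).
#'
#' @param kind One of `r paste(ANNOTATION_KINDS, collapse = ", ")`.
#' @param value Non-empty identifier string.
#' @param label Optional free-text label.
#' @return An object of class `annotation`.
#' @export
annotation <- function(kind, value, label = NA_character_) {
  if (!is_string(kind) || !(kind %in% ANNOTATION_KINDS)) {
    abort_validation(sprintf("annotation kind must be one of: %s",
                             paste(ANNOTATION_KINDS, collapse = ", ")))
  }
  if (!is_string(value) || !nzchar(value)) {
    abort_validation("annotation value must be a non-empty string")
  }
  structure(list(kind = kind, value = value, label = as.character(label)),
            class = "annotation")
}

#' One provider's verdict on a dataset
#'
#' @param provider_id Provider identifier.
#' @param status A [status_code()].
#' @param scored_pairs List of entries `list(pair =, score =, annotations =)`.
#' @return An object of class `provider_result`.
#' @export
provider_result <- function(provider_id, status, scored_pairs = list()) {
  if (!is_string(provider_id)) abort_validation("provider_id must be a string")
  if (!inherits(status, "status_code")) abort_validation("status must be a status_code")
  if (status$code == 0L && !length(scored_pairs)) {
    abort_validation("a status-0 provider result must score every input pair")
  }
  structure(list(provider_id = provider_id, status = status,
                 scored_pairs = scored_pairs),
            class = "provider_result")
}

#' @export
print.drug_event_pair <- function(x, ...) {
  cat(sprintf("<pair %s / %s>%s\n", x$drug$atc_code, x$event$event_code,
              if (is.null(x$mining_stats)) "" else
                sprintf(" +%d stats", length(x$mining_stats))))
  invisible(x)
}

#' @export
print.provider_result <- function(x, ...) {
  cat(sprintf("<provider_result %s> status %d (%s), %d scored pair(s)\n",
              x$provider_id, x$status$code, x$status$message,
              length(x$scored_pairs)))
  invisible(x)
}

#' Read a drug-event pair dataset from CSV
#'
#' Expected columns: `atc_code, drug_name, event_code, event_name` plus any
#' number of `stat:<name>` columns carrying numeric mining statistics.
#'
#' @param path CSV file path (UTF-8, header required).
#' @return A [pair_dataset()].
#' @export
read_pairs_csv <- function(path) {
  if (!file.exists(path)) abort_not_found(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  required <- c("atc_code", "drug_name", "event_code", "event_name")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort_parse(sprintf("pair CSV missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  stat_cols <- grep("^stat:", names(df), value = TRUE)
  pairs <- lapply(seq_len(nrow(df)), function(i) {
    stats <- NULL
    if (length(stat_cols)) {
      vals <- suppressWarnings(as.numeric(df[i, stat_cols]))
      keep <- !is.na(vals)
      if (any(keep)) {
        stats <- as.list(vals[keep])
        names(stats) <- sub("^stat:", "", stat_cols[keep])
      }
    }
    make_pair(drug_ref(df$atc_code[i], empty_to_na(df$drug_name[i])),
              event_ref(df$event_code[i], empty_to_na(df$event_name[i])),
              mining_stats = stats)
  })
  pair_dataset(pairs)
}

#' Write a drug-event pair dataset to CSV
#'
#' @param pairs A [pair_dataset()] or plain list of pairs.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pairs_csv <- function(pairs, path) {
  stat_names <- sort(unique(unlist(lapply(pairs, function(p)
    names(p$mining_stats)))))
  header <- c("atc_code", "drug_name", "event_code", "event_name",
              if (length(stat_names)) paste0("stat:", stat_names))
  rows <- vapply(pairs, function(p) {
    stats <- vapply(stat_names, function(s) {
      v <- p$mining_stats[[s]]
      if (is.null(v)) "" else format(v, digits = 15, scientific = FALSE)
    }, character(1))
    paste(c(csv_field(p$drug$atc_code), csv_field(na_to_empty(p$drug$name)),
            csv_field(p$event$event_code), csv_field(na_to_empty(p$event$name)),
            csv_field(stats)), collapse = ",")
  }, character(1))
  write_lines(c(paste(csv_field(header), collapse = ","), rows), path)
  invisible(path)
}

empty_to_na <- function(x) if (!length(x) || is.na(x) || !nzchar(x)) NA_character_ else x
na_to_empty <- function(x) if (length(x) != 1L || is.na(x)) "" else x

csv_field <- function(x) {
  x <- as.character(x)
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

write_lines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Default bundled event vocabulary
#'
#' Eleven adverse events with synthetic codes and names, matching the size
#' of the event panel used in drug studies. The bundled names are
#' package-invented placeholders, not any project's official event list.
#'
#' @return A data frame with columns `event_code`, `name`.
#' @export
default_event_vocabulary <- function() {
  path <- system.file("extdata", "events.csv", package = "adrsub",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
}

vocabulary_to_events <- function(vocabulary) {
  if (is.data.frame(vocabulary)) {
    if (!all(c("event_code", "name") %in% names(vocabulary))) {
      abort_validation("event vocabulary needs columns event_code, name")
    }
    return(lapply(seq_len(nrow(vocabulary)), function(i)
      event_ref(vocabulary$event_code[i], vocabulary$name[i])))
  }
  if (is.list(vocabulary) &&
      all(vapply(vocabulary, inherits, logical(1), "event_ref"))) {
    return(vocabulary)
  }
  abort_validation("vocabulary must be a data frame or list of event_ref")
}
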