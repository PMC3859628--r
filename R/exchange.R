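# The provider interchange dialect. Documents travel between the engine
# and the knowledge providers as canonical XML with three concerns:
# monitoring (status codes), scoring (the [0,1] score per signal) and
# annotation (typed evidence links). The writer emits one fixed canonical
# byte form: fixed element order, two-space indent, UTF-8, LF line ends,
# scores with exactly 6 fractional digits. The machine-readable schema
# ships at inst/schema/euadr-dataset.xsd.

#' Build an input exchange document
#'
#' @param pairs A [pair_dataset()] or list of [make_pair()] objects.
#' @return An object of class `exchange_document` with `direction = "input"`.
#' @export
exchange_input <- function(pairs) {
  if (!inherits(pairs, "pair_dataset")) pairs <- pair_dataset(pairs)
  structure(list(direction = "input", provider_id = NULL, monitoring = NULL,
                 signals = lapply(pairs, function(p)
                   list(pair = p, score = NULL, annotations = list()))),
            class = "exchange_document")
}

#' Build an output exchange document
#'
#' @param provider_id Identifier of the provider emitting the document.
#' @param status A [status_code()]; mandatory monitoring section.
#' @param signals List of entries `list(pair =, score =, annotations =)`;
#'   empty when the status is a failure.
#' @return An `exchange_document` with `direction = "output"`.
#' @export
exchange_output <- function(provider_id, status, signals = list()) {
  if (!is_string(provider_id)) abort_validation("provider_id must be a string")
  if (!inherits(status, "status_code")) {
    abort_validation("output documents require a status_code monitoring section")
  }
  structure(list(direction = "output", provider_id = provider_id,
                 monitoring = status, signals = signals),
            class = "exchange_document")
}

xml_escape_attr <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

# 6 fractional digits; C printf rounding (round-half-even on the binary
# value), so identical doubles always print identically.
format_score <- function(x) sprintf("%.6f", x)

attr_str <- function(name, value) {
  sprintf(' %s="%s"', name, xml_escape_attr(value))
}

opt_name_attr <- function(name) {
  if (length(name) == 1L && !is.na(name) && nzchar(name)) attr_str("name", name) else ""
}

#' Serialize an exchange document to its canonical byte form
#'
#' The writer is deterministic: structurally identical documents always
#' produce identical bytes. Serialization is refused, with a diagnostic
#' naming the first offending element, for documents violating the dialect
#' invariants (scores outside \[0,1\], duplicate pairs, missing monitoring
#' section on an output document, and so on).
#'
#' @param doc An `exchange_document`.
#' @return A single string of canonical XML (UTF-8, LF line ends).
#' @seealso [write_document()] to write to a file, [read_document()].
#' @export
format_document <- function(doc) {
  if (!inherits(doc, "exchange_document")) {
    abort_validation("not an exchange_document")
  }
  check_document_object(doc)
  out <- character(0)
  push <- function(...) out[[length(out) + 1L]] <<- sprintf(...)
  push('<?xml version="1.0" encoding="UTF-8"?>')
  root_attrs <- attr_str("direction", doc$direction)
  if (doc$direction == "output") {
    root_attrs <- paste0(root_attrs, attr_str("provider", doc$provider_id))
  }
  push("<euadr-dataset%s>", root_attrs)
  if (doc$direction == "output") {
    push('  <monitoring%s%s/>',
         attr_str("code", as.character(doc$monitoring$code)),
         attr_str("message", doc$monitoring$message))
  }
  if (!length(doc$signals)) {
    push("  <signals/>")
  } else {
    push("  <signals>")
    for (entry in doc$signals) {
      push("    <signal>")
      push("      <drug%s%s/>", attr_str("atc", entry$pair$drug$atc_code),
           opt_name_attr(entry$pair$drug$name))
      push("      <event%s%s/>", attr_str("code", entry$pair$event$event_code),
           opt_name_attr(entry$pair$event$name))
      stats <- entry$pair$mining_stats
      if (!is.null(stats) && length(stats)) {
        push("      <stats>")
        for (nm in names(stats)) {
          push("        <stat%s%s/>", attr_str("name", nm),
               attr_str("value", format_score(stats[[nm]])))
        }
        push("      </stats>")
      }
      if (!is.null(entry$score)) {
        push("      <score%s/>", attr_str("value", format_score(entry$score)))
      }
      if (length(entry$annotations)) {
        push("      <annotations>")
        for (ann in entry$annotations) {
          push("        <annotation%s%s%s/>", attr_str("kind", ann$kind),
               attr_str("value", ann$value),
               if (length(ann$label) == 1L && !is.na(ann$label))
                 attr_str("label", ann$label) else "")
        }
        push("      </annotations>")
      }
      push("    </signal>")
    }
    push("  </signals>")
  }
  push("</euadr-dataset>")
  paste0(paste(out, collapse = "\n"), "\n")
}

# Object-level invariants, checked before serialization. Diagnostics name
# the first offending element.
check_document_object <- function(doc) {
  if (!doc$direction %in% c("input", "output")) {
    abort_validation("exchange document direction must be 'input' or 'output'")
  }
  if (doc$direction == "output" && !inherits(doc$monitoring, "status_code")) {
    abort_validation("<monitoring>: output documents must carry a monitoring section")
  }
  if (doc$direction == "input" && !is.null(doc$monitoring)) {
    abort_validation("<monitoring>: input documents must not carry a monitoring section")
  }
  keys <- character(0)
  for (i in seq_along(doc$signals)) {
    entry <- doc$signals[[i]]
    el <- sprintf("<signal> #%d", i)
    if (!inherits(entry$pair, "drug_event_pair")) {
      abort_validation(sprintf("%s: missing drug-event pair", el))
    }
    if (doc$direction == "input" && !is.null(entry$score)) {
      abort_validation(sprintf("%s <score>: input documents never carry scores", el))
    }
    if (!is.null(entry$score)) {
      s <- as.numeric(entry$score)
      if (is.na(s) || s < 0 || s > 1) {
        abort_validation(sprintf("%s <score>: value outside [0,1]", el))
      }
    }
    for (ann in entry$annotations) {
      if (!inherits(ann, "annotation")) {
        abort_validation(sprintf("%s <annotation>: not an annotation object", el))
      }
    }
    keys <- c(keys, pair_key(entry$pair))
  }
  if (anyDuplicated(keys)) {
    abort_validation(sprintf("<signal>: duplicate drug-event pair %s",
                             gsub("\x1f", "/", keys[duplicated(keys)][1])))
  }
  invisible(TRUE)
}

#' Write an exchange document to a file
#'
#' @param doc An `exchange_document`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_document <- function(doc, path) {
  bytes <- charToRaw(format_document(doc))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(bytes, con)
  invisible(path)
}

read_xml_input <- function(x) {
  tryCatch({
    if (inherits(x, "xml_document")) x
    else if (is.raw(x)) xml2::read_xml(x)
    else if (is_string(x) && file.exists(x)) xml2::read_xml(x)
    else xml2::read_xml(x)
  }, error = function(e) {
    abort_parse(sprintf("malformed XML: %s", conditionMessage(e)))
  })
}

diag_row <- function(path, rule, message) {
  data.frame(path = path, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

# Shared structural/content checker over the parsed XML tree. Returns a
# diagnostics data frame; each rule id corresponds to exactly one dialect
# invariant (documented in inst/schema/euadr-dataset.xsd).
collect_diagnostics <- function(xml) {
  d <- list()
  add <- function(path, rule, message) d[[length(d) + 1L]] <<- diag_row(path, rule, message)

  root <- xml2::xml_root(xml)
  if (xml2::xml_name(root) != "euadr-dataset") {
    add("/", "root-name", "root element must be <euadr-dataset>")
    return(do.call(rbind, d))
  }
  direction <- xml2::xml_attr(root, "direction")
  if (is.na(direction) || !direction %in% c("input", "output")) {
    add("/euadr-dataset", "direction-attr",
        "direction attribute must be 'input' or 'output'")
    direction <- NA_character_
  }
  provider <- xml2::xml_attr(root, "provider")
  if (identical(direction, "output") && (is.na(provider) || !nzchar(provider))) {
    add("/euadr-dataset", "provider-required",
        "output documents must carry a provider attribute")
  }
  if (identical(direction, "input") && !is.na(provider)) {
    add("/euadr-dataset", "provider-unexpected",
        "input documents must not carry a provider attribute")
  }

  children <- xml2::xml_children(root)
  child_names <- xml2::xml_name(children)
  known_top <- c("monitoring", "signals")
  for (nm in setdiff(unique(child_names), known_top)) {
    add(paste0("/euadr-dataset/", nm), "unknown-element",
        sprintf("unknown element <%s>", nm))
  }
  mon <- children[child_names == "monitoring"]
  if (identical(direction, "output")) {
    if (length(mon) != 1L) {
      add("/euadr-dataset/monitoring", "monitoring-required",
          "output documents must carry exactly one monitoring section")
    } else {
      code <- suppressWarnings(as.integer(xml2::xml_attr(mon[[1]], "code")))
      if (is.na(code)) {
        add("/euadr-dataset/monitoring", "status-registered",
            "monitoring code must be an integer")
      } else if (!exists(as.character(code), envir = .status_registry,
                         inherits = FALSE)) {
        add("/euadr-dataset/monitoring", "status-registered",
            sprintf("status code %d is not registered", code))
      }
    }
  } else if (length(mon)) {
    add("/euadr-dataset/monitoring", "monitoring-unexpected",
        "input documents must not carry a monitoring section")
  }

  signals_el <- children[child_names == "signals"]
  if (length(signals_el) != 1L) {
    add("/euadr-dataset/signals", "signals-required",
        "document must carry exactly one <signals> section")
    return(do.call(rbind, d))
  }

  keys <- character(0)
  signal_nodes <- xml2::xml_children(signals_el[[1]])
  for (i in seq_along(signal_nodes)) {
    node <- signal_nodes[[i]]
    spath <- sprintf("/euadr-dataset/signals/signal[%d]", i)
    if (xml2::xml_name(node) != "signal") {
      add(spath, "unknown-element",
          sprintf("unknown element <%s> under <signals>", xml2::xml_name(node)))
      next
    }
    kids <- xml2::xml_children(node)
    knames <- xml2::xml_name(kids)
    for (nm in setdiff(unique(knames),
                       c("drug", "event", "stats", "score", "annotations"))) {
      add(paste0(spath, "/", nm), "unknown-element",
          sprintf("unknown element <%s> under <signal>", nm))
    }
    expected_order <- intersect(c("drug", "event", "stats", "score", "annotations"),
                                knames)
    if (!identical(knames[knames %in% expected_order], expected_order)) {
      add(spath, "element-order",
          "signal children must appear in order drug, event, stats, score, annotations")
    }

    drug <- kids[knames == "drug"]
    event <- kids[knames == "event"]
    if (length(drug) != 1L) {
      add(paste0(spath, "/drug"), "drug-required",
          "each signal must carry exactly one <drug>")
    } else {
      atc <- xml2::xml_attr(drug[[1]], "atc")
      if (is.na(atc) || !validate_atc(atc)) {
        add(paste0(spath, "/drug"), "atc-format",
            sprintf("invalid ATC code %s", sQuote(atc)))
      }
    }
    if (length(event) != 1L) {
      add(paste0(spath, "/event"), "event-required",
          "each signal must carry exactly one <event>")
    } else {
      code <- xml2::xml_attr(event[[1]], "code")
      if (is.na(code) || !nzchar(code)) {
        add(paste0(spath, "/event"), "event-code-nonempty",
            "event code attribute must be non-empty")
      }
    }
    if (length(drug) == 1L && length(event) == 1L) {
      keys <- c(keys, paste(xml2::xml_attr(drug[[1]], "atc"),
                            xml2::xml_attr(event[[1]], "code"), sep = "\x1f"))
    }

    score_nodes <- kids[knames == "score"]
    if (length(score_nodes) && identical(direction, "input")) {
      add(paste0(spath, "/score"), "score-in-input",
          "input documents never carry scores")
    }
    for (sn in score_nodes) {
      v <- suppressWarnings(as.numeric(xml2::xml_attr(sn, "value")))
      if (is.na(v) || v < 0 || v > 1) {
        add(paste0(spath, "/score"), "score-range",
            sprintf("score value %s outside [0,1]",
                    sQuote(xml2::xml_attr(sn, "value"))))
      }
    }
    for (st_parent in kids[knames == "stats"]) {
      for (st in xml2::xml_children(st_parent)) {
        v <- suppressWarnings(as.numeric(xml2::xml_attr(st, "value")))
        if (is.na(v)) {
          add(paste0(spath, "/stats/stat"), "stat-numeric",
              "stat value must be numeric")
        }
      }
    }
    for (ann_parent in kids[knames == "annotations"]) {
      anns <- xml2::xml_children(ann_parent)
      for (j in seq_along(anns)) {
        apath <- sprintf("%s/annotations/annotation[%d]", spath, j)
        kind <- xml2::xml_attr(anns[[j]], "kind")
        value <- xml2::xml_attr(anns[[j]], "value")
        if (is.na(kind) || !kind %in% ANNOTATION_KINDS) {
          add(apath, "annotation-kind",
              sprintf("annotation kind %s not in the closed set", sQuote(kind)))
        }
        if (is.na(value) || !nzchar(value)) {
          add(apath, "annotation-value", "annotation value must be non-empty")
        }
      }
    }
  }
  if (anyDuplicated(keys)) {
    dup <- keys[duplicated(keys)][1]
    add("/euadr-dataset/signals", "pair-unique",
        sprintf("duplicate drug-event pair %s", gsub("\x1f", "/", dup)))
  }
  if (!length(d)) {
    return(data.frame(path = character(0), rule = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, d)
}

#' Validate an exchange document, returning diagnostics
#'
#' Unlike [read_document()], validation never throws on content problems:
#' it returns one diagnostic row per violated rule, with the element path,
#' a stable rule id, and a message. An empty data frame means the document
#' is canonical-valid.
#'
#' @param x File path, XML string, raw vector, or parsed `xml_document`.
#' @return Data frame with columns `path`, `rule`, `message`.
#' @export
validate_document <- function(x) {
  xml <- tryCatch(read_xml_input(x), adrsub_parse_error = function(e) e)
  if (inherits(xml, "adrsub_parse_error")) {
    return(diag_row("/", "xml-well-formed", conditionMessage(xml)))
  }
  collect_diagnostics(xml)
}

#' Parse an exchange document
#'
#' Strict mode (the default) rejects any element not in the dialect;
#' lenient mode ignores unknown elements with a warning. All other
#' invariants (score range, pair uniqueness, monitoring presence, status
#' registration) are always enforced.
#'
#' @param x File path, XML string, raw vector, or parsed `xml_document`.
#' @param mode `"strict"` or `"lenient"`.
#' @return An `exchange_document`, the exact inverse of [format_document()]
#'   on canonical bytes.
#' @export
read_document <- function(x, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  xml <- read_xml_input(x)
  diags <- collect_diagnostics(xml)
  if (mode == "lenient" && nrow(diags)) {
    unknown <- diags$rule == "unknown-element"
    if (any(unknown)) {
      warning(sprintf("ignoring unknown element(s): %s",
                      paste(diags$path[unknown], collapse = ", ")),
              call. = FALSE)
      diags <- diags[!unknown, , drop = FALSE]
    }
  }
  if (nrow(diags)) {
    abort_validation(paste0("invalid exchange document:\n", paste(
      sprintf("  [%s] %s: %s", diags$rule, diags$path, diags$message),
      collapse = "\n")), diagnostics = diags)
  }

  root <- xml2::xml_root(xml)
  direction <- xml2::xml_attr(root, "direction")
  signals <- lapply(xml2::xml_find_all(xml, "/euadr-dataset/signals/signal"),
                    function(node) {
    drug_node <- xml2::xml_find_first(node, "./drug")
    event_node <- xml2::xml_find_first(node, "./event")
    stats_nodes <- xml2::xml_find_all(node, "./stats/stat")
    stats <- NULL
    if (length(stats_nodes)) {
      stats <- as.list(as.numeric(xml2::xml_attr(stats_nodes, "value")))
      names(stats) <- xml2::xml_attr(stats_nodes, "name")
    }
    pair <- make_pair(
      drug_ref(xml2::xml_attr(drug_node, "atc"),
               attr_or_na(drug_node, "name")),
      event_ref(xml2::xml_attr(event_node, "code"),
                attr_or_na(event_node, "name")),
      mining_stats = stats)
    score_node <- xml2::xml_find_first(node, "./score")
    s <- if (inherits(score_node, "xml_missing")) NULL else
      as.numeric(xml2::xml_attr(score_node, "value"))
    anns <- lapply(xml2::xml_find_all(node, "./annotations/annotation"),
                   function(a) annotation(xml2::xml_attr(a, "kind"),
                                          xml2::xml_attr(a, "value"),
                                          attr_or_na(a, "label")))
    list(pair = pair, score = s, annotations = anns)
  })

  if (direction == "input") {
    exchange_input(lapply(signals, `[[`, "pair"))
  } else {
    mon <- xml2::xml_find_first(xml, "/euadr-dataset/monitoring")
    exchange_output(xml2::xml_attr(root, "provider"),
                    status_code(as.integer(xml2::xml_attr(mon, "code")),
                                xml2::xml_attr(mon, "message")),
                    signals)
  }
}

attr_or_na <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NA_character_ else v
}

#' @export
print.exchange_document <- function(x, ...) {
  cat(sprintf("<exchange_document %s%s> %d signal(s)%s\n", x$direction,
              if (!is.null(x$provider_id)) paste0(" from ", x$provider_id) else "",
              length(x$signals),
              if (!is.null(x$monitoring))
                sprintf(", status %d", x$monitoring$code) else ""))
  invisible(x)
}
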