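# Seeded synthetic knowledge world. Emulates every knowledge source the
# providers consume -- literature annotation index, per-resource
# co-occurrence counts, target profiles with a pathway map -- with a set
# of planted true drug-event associations, so the whole pipeline is
# testable offline with a known ground truth.

#' Synthetic-world configuration
#'
#' Sizes and planted-effect settings for [generate_world()]. The `strong`
#' preset gives planted pairs Poisson(6) supporting publications (at least
#' 3 with probability above 0.9), joint document counts inflated 5x over
#' the independence expectation, and 1-3 dedicated shared target proteins
#' with probability 0.95; null pairs get Poisson(0.2) supporting
#' publications, joint counts at the rounded independence expectation, and
#' only chance-level profile overlap (about 3% with the default profile
#' and pool sizes). The `weak` preset halves these effects to demonstrate
#' graded behaviour.
#'
#' @param seed Integer seed; the world is a deterministic function of it.
#' @param n_drugs,n_events Vocabulary sizes (an 11-event vocabulary uses
#'   the bundled default panel).
#' @param n_planted Number of planted true associations.
#' @param preset `"strong"` or `"weak"` effect preset.
#' @param n_publications Background (irrelevant) publications added to the
#'   literature index.
#' @param corpus_N Total document count per co-occurrence resource.
#' @param n_proteins Protein-accession pool size.
#' @param n_pathways Pathway-identifier pool size.
#' @param profile_size Baseline proteins per drug/event profile.
#' @return An object of class `world_config`.
#' @export
world_config <- function(seed = 42, n_drugs = 5, n_events = 11,
                         n_planted = 10, preset = c("strong", "weak"),
                         n_publications = 100, corpus_N = 2000,
                         n_proteins = 500, n_pathways = 40,
                         profile_size = 4) {
  preset <- match.arg(preset)
  cfg <- list(seed = as.numeric(seed), n_drugs = as.numeric(n_drugs),
              n_events = as.numeric(n_events),
              n_planted = as.numeric(n_planted), preset = preset,
              n_publications = as.numeric(n_publications),
              corpus_N = as.numeric(corpus_N),
              n_proteins = as.numeric(n_proteins),
              n_pathways = as.numeric(n_pathways),
              profile_size = as.numeric(profile_size))
  effects <- switch(preset,
    strong = list(planted_pub_lambda = 6, null_pub_lambda = 0.2,
                  joint_inflation = 5, planted_shared_prob = 0.95),
    weak = list(planted_pub_lambda = 2, null_pub_lambda = 0.5,
                joint_inflation = 2, planted_shared_prob = 0.6))
  cfg <- c(cfg, effects)
  sizes <- cfg[c("n_drugs", "n_events", "n_planted", "n_publications",
                 "corpus_N", "n_proteins", "n_pathways", "profile_size")]
  if (any(vapply(sizes, function(v) is.na(v) || v < 0, logical(1))) ||
      any(unlist(sizes[c("n_drugs", "n_events", "corpus_N", "n_proteins",
                         "n_pathways", "profile_size")]) < 1)) {
    abort_config("all world sizes must be positive")
  }
  if (cfg$n_planted > cfg$n_drugs * cfg$n_events) {
    abort_config("n_planted exceeds the drug x event grid")
  }
  if (3 * cfg$n_planted + cfg$profile_size > cfg$n_proteins) {
    abort_config("protein pool too small for the requested planting")
  }
  structure(cfg, class = "world_config")
}

with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

make_drug_vocabulary <- function(n) {
  data.frame(
    atc_code = vapply(seq_len(n), function(i)
      sprintf("%s10AB%02d", LETTERS[((i - 1) %% 26) + 1],
              ((i - 1) %/% 26) + 1), character(1)),
    name = sprintf("drug-%03d", seq_len(n)),
    stringsAsFactors = FALSE)
}

make_event_vocabulary <- function(n) {
  if (n == 11) {
    df <- default_event_vocabulary()
    return(data.frame(event_code = df$event_code, name = df$name,
                      stringsAsFactors = FALSE))
  }
  data.frame(event_code = sprintf("EV%02d", seq_len(n)),
             name = sprintf("event-%02d", seq_len(n)),
             stringsAsFactors = FALSE)
}

split_to_sorted_list <- function(values, keys) {
  if (!length(keys)) return(structure(list(), names = character(0)))
  out <- split(values, keys)
  out <- out[sort(names(out))]
  lapply(out, function(v) sort(unique(as.character(v))))
}

#' Generate a synthetic knowledge world
#'
#' Deterministic given the configured seed: the same configuration always
#' yields an identical world (and identical files via [write_world()]).
#'
#' @param config A [world_config()].
#' @return An object of class `knowledge_world` with fields `drugs`,
#'   `events`, `literature`, `corpus`, `drug_profiles`, `event_profiles`,
#'   `pathway_map`, `planted`, `config`.
#' @examples
#' world <- generate_world(world_config(seed = 1, n_drugs = 2, n_events = 3,
#'                                      n_planted = 1))
#' nrow(world$planted)
#' @export
generate_world <- function(config = world_config()) {
  if (!inherits(config, "world_config")) abort_config("config must be a world_config")
  with_local_seed(config$seed, {
    drugs <- make_drug_vocabulary(config$n_drugs)
    events <- make_event_vocabulary(config$n_events)
    grid <- expand.grid(atc_code = drugs$atc_code,
                        event_code = events$event_code,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[order(grid$atc_code, grid$event_code), , drop = FALSE]
    rownames(grid) <- NULL
    planted_idx <- if (config$n_planted > 0) {
      sort(sample.int(nrow(grid), config$n_planted))
    } else integer(0)
    planted <- grid[planted_idx, , drop = FALSE]
    rownames(planted) <- NULL
    is_planted <- seq_len(nrow(grid)) %in% planted_idx

    # --- literature index -------------------------------------------------
    drug_map <- stats::setNames(paste0("D_", drugs$atc_code), drugs$atc_code)
    event_map <- stats::setNames(paste0("E_", events$event_code),
                                 events$event_code)
    records <- list()
    bg_desc <- sprintf("X_%03d", 1:50)
    add_record <- function(annotations) {
      id <- sprintf("%08d", 10000000 + length(records) + 1)
      records[[id]] <<- data.frame(
        descriptor = vapply(annotations, `[[`, character(1), 1),
        qualifier = vapply(annotations, `[[`, character(1), 2),
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(grid))) {
      lambda <- if (is_planted[i]) config$planted_pub_lambda else
        config$null_pub_lambda
      k <- stats::rpois(1, lambda)
      dd <- drug_map[[grid$atc_code[i]]]
      ed <- event_map[[grid$event_code[i]]]
      for (j in seq_len(k)) {
        core <- if (j %% 2L == 1L) {
          list(c(dd, QUALIFIER_ADVERSE_EFFECTS), c(ed, NA_character_))
        } else {
          list(c(ed, QUALIFIER_CHEMICALLY_INDUCED), c(dd, NA_character_))
        }
        extra <- lapply(sample(bg_desc, sample(1:2, 1)), function(x)
          c(x, NA_character_))
        add_record(c(core, extra))
      }
    }
    for (b in seq_len(config$n_publications)) {
      anns <- lapply(sample(bg_desc, sample(2:4, 1)), function(x)
        c(x, sample(c(NA_character_, QUALIFIER_ADVERSE_EFFECTS,
                      QUALIFIER_CHEMICALLY_INDUCED), 1)))
      add_record(anns)
    }
    pharm_actions <- split_to_sorted_list(
      rep("PA_class_01", nrow(drugs)), unname(drug_map))
    literature <- literature_index(records, drug_map, event_map,
                                   pharm_actions)

    # --- co-occurrence counts --------------------------------------------
    corpus <- list()
    for (res in sort(COOC_RESOURCES)) {
      N <- config$corpus_N
      n_d <- stats::setNames(as.numeric(sample(40:80, nrow(drugs),
                                               replace = TRUE)),
                             drugs$atc_code)
      n_e <- stats::setNames(as.numeric(sample(40:80, nrow(events),
                                               replace = TRUE)),
                             events$event_code)
      joint <- grid
      joint$count <- vapply(seq_len(nrow(grid)), function(i) {
        expected <- n_d[[grid$atc_code[i]]] * n_e[[grid$event_code[i]]] / N
        if (is_planted[i]) {
          min(n_d[[grid$atc_code[i]]], n_e[[grid$event_code[i]]],
              ceiling(config$joint_inflation * expected) + 1)
        } else {
          round(expected)
        }
      }, numeric(1))
      names(joint) <- c("drug", "event", "count")
      corpus[[res]] <- corpus_counts(res, N, n_d, n_e, joint)
    }

    # --- target profiles and pathway map ---------------------------------
    proteins <- sprintf("P%05d", seq_len(config$n_proteins))
    n_reserved <- 3 * config$n_planted
    base_pool <- proteins[seq_len(config$n_proteins - n_reserved)]
    reserved <- proteins[seq.int(config$n_proteins - n_reserved + 1,
                                 length.out = n_reserved)]
    drug_prof <- lapply(stats::setNames(drugs$atc_code, drugs$atc_code),
                        function(a) sample(base_pool, config$profile_size))
    event_prof <- lapply(stats::setNames(events$event_code,
                                         events$event_code),
                         function(e) sample(base_pool, config$profile_size))
    if (nrow(planted)) {
      for (i in seq_len(nrow(planted))) {
        if (stats::runif(1) <= config$planted_shared_prob) {
          k <- sample(1:3, 1)
          shared <- reserved[3 * (i - 1) + seq_len(k)]
          drug_prof[[planted$atc_code[i]]] <-
            c(drug_prof[[planted$atc_code[i]]], shared)
          event_prof[[planted$event_code[i]]] <-
            c(event_prof[[planted$event_code[i]]], shared)
        }
      }
    }
    drug_prof <- lapply(drug_prof, function(v) sort(unique(v)))
    event_prof <- lapply(event_prof, function(v) sort(unique(v)))
    drug_prof <- drug_prof[sort(names(drug_prof))]
    event_prof <- event_prof[sort(names(event_prof))]

    pathways <- sprintf("R-HSA-%04d", seq_len(config$n_pathways))
    pw_rows <- list()
    for (p in proteins) {
      if (stats::runif(1) < 0.7) {
        pw_rows[[p]] <- sample(pathways, sample(1:2, 1))
      }
    }
    pathway_map <- split_to_sorted_list(
      unlist(pw_rows, use.names = FALSE),
      rep(names(pw_rows), lengths(pw_rows)))

    structure(list(drugs = drugs, events = events, literature = literature,
                   corpus = corpus, drug_profiles = drug_prof,
                   event_profiles = event_prof, pathway_map = pathway_map,
                   planted = planted, config = config),
              class = "knowledge_world")
  })
}

#' @export
print.knowledge_world <- function(x, ...) {
  cat(sprintf(paste0("<knowledge_world> %d drugs x %d events, %d planted; ",
                     "%d publications, %d resource index(es), %d+%d profiles\n"),
              nrow(x$drugs), nrow(x$events), nrow(x$planted),
              length(x$literature$records), length(x$corpus),
              length(x$drug_profiles), length(x$event_profiles)))
  invisible(x)
}

#' All drug-event pairs of a world, with planted-truth labels
#'
#' @param world A `knowledge_world`.
#' @return List with `pairs` (a [pair_dataset()] over the full grid, drugs
#'   then events in vocabulary order) and `planted` (logical vector).
#' @export
world_pairs <- function(world) {
  grid <- expand.grid(atc_code = world$drugs$atc_code,
                      event_code = world$events$event_code,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$atc_code, grid$event_code), , drop = FALSE]
  planted_keys <- paste(world$planted$atc_code, world$planted$event_code)
  pairs <- lapply(seq_len(nrow(grid)), function(i) {
    make_pair(
      drug_ref(grid$atc_code[i],
               world$drugs$name[match(grid$atc_code[i], world$drugs$atc_code)]),
      event_ref(grid$event_code[i],
                world$events$name[match(grid$event_code[i],
                                        world$events$event_code)]))
  })
  list(pairs = pair_dataset(pairs),
       planted = paste(grid$atc_code, grid$event_code) %in% planted_keys)
}

# ---- persistence ---------------------------------------------------------

write_csv_canonical <- function(df, path) {
  lines <- c(paste(csv_field(names(df)), collapse = ","),
             vapply(seq_len(nrow(df)), function(i)
               paste(csv_field(vapply(df[i, , drop = FALSE], function(v)
                 if (is.numeric(v)) format(v, digits = 15, scientific = FALSE)
                 else as.character(v), character(1))), collapse = ","),
               character(1)))
  write_lines(lines, path)
}

read_csv_chr <- function(path, numeric_cols = character(0)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (col in numeric_cols) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Write a knowledge world to a directory
#'
#' Plain-text layout: `world.json` (config manifest), `drugs.csv`,
#' `events.csv`, `planted.csv`; `literature.jsonl` (one JSON record per
#' publication) with `drug_descriptors.csv`, `event_descriptors.csv`,
#' `pharm_actions.csv`; `cooccurrence/<resource>_{terms,joint}.csv` plus
#' `<resource>_total.txt`; `targets/{drug,event}_profiles.csv` and
#' `targets/pathways.csv`. Output is byte-deterministic for a given world.
#'
#' @param world A `knowledge_world`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(config = unclass(world$config)),
                       file.path(dir, "world.json"), auto_unbox = TRUE,
                       digits = NA)
  write_csv_canonical(world$drugs, file.path(dir, "drugs.csv"))
  write_csv_canonical(world$events, file.path(dir, "events.csv"))
  write_csv_canonical(world$planted, file.path(dir, "planted.csv"))

  lit <- world$literature
  if (!is.null(lit)) {
    lines <- vapply(names(lit$records), function(id) {
      rec <- lit$records[[id]]
      anns <- lapply(seq_len(nrow(rec)), function(i) {
        q <- rec$qualifier[i]
        list(descriptor = rec$descriptor[i],
             qualifier = if (is.na(q)) NULL else q)
      })
      as.character(jsonlite::toJSON(list(pmid = id, annotations = anns),
                                    auto_unbox = TRUE, null = "null"))
    }, character(1))
    write_lines(lines, file.path(dir, "literature.jsonl"))
    write_csv_canonical(
      data.frame(atc_code = names(lit$drug_map),
                 descriptor = unname(lit$drug_map),
                 stringsAsFactors = FALSE),
      file.path(dir, "drug_descriptors.csv"))
    write_csv_canonical(
      data.frame(event_code = names(lit$event_map),
                 descriptor = unname(lit$event_map),
                 stringsAsFactors = FALSE),
      file.path(dir, "event_descriptors.csv"))
    pa <- world$literature$pharm_actions
    write_csv_canonical(
      data.frame(descriptor = rep(names(pa), lengths(pa)),
                 action = unlist(pa, use.names = FALSE),
                 stringsAsFactors = FALSE),
      file.path(dir, "pharm_actions.csv"))
  }

  if (!is.null(world$corpus)) {
    cdir <- file.path(dir, "cooccurrence")
    dir.create(cdir, showWarnings = FALSE)
    for (res in names(world$corpus)) {
      cc <- world$corpus[[res]]
      terms <- rbind(
        data.frame(term_type = "drug", term = names(cc$drug_counts),
                   count = unname(cc$drug_counts), stringsAsFactors = FALSE),
        data.frame(term_type = "event", term = names(cc$event_counts),
                   count = unname(cc$event_counts), stringsAsFactors = FALSE))
      write_csv_canonical(terms, file.path(cdir, paste0(res, "_terms.csv")))
      write_csv_canonical(cc$joint, file.path(cdir, paste0(res, "_joint.csv")))
      write_lines(as.character(cc$N),
                  file.path(cdir, paste0(res, "_total.txt")))
    }
  }

  if (!is.null(world$drug_profiles) || !is.null(world$event_profiles)) {
    tdir <- file.path(dir, "targets")
    dir.create(tdir, showWarnings = FALSE)
    prof_df <- function(prof) data.frame(
      entity_id = rep(names(prof), lengths(prof)),
      protein = unlist(prof, use.names = FALSE), stringsAsFactors = FALSE)
    write_csv_canonical(prof_df(world$drug_profiles),
                        file.path(tdir, "drug_profiles.csv"))
    write_csv_canonical(prof_df(world$event_profiles),
                        file.path(tdir, "event_profiles.csv"))
    if (!is.null(world$pathway_map)) {
      pw <- world$pathway_map
      write_csv_canonical(
        data.frame(protein = rep(names(pw), lengths(pw)),
                   pathway = unlist(pw, use.names = FALSE),
                   stringsAsFactors = FALSE),
        file.path(tdir, "pathways.csv"))
    }
  }
  invisible(dir)
}

#' Load a knowledge world from a directory
#'
#' The inverse of [write_world()]. Core files (`world.json`, `drugs.csv`,
#' `events.csv`) are mandatory; missing knowledge-source components load
#' as `NULL` (a partial world), which the corresponding provider later
#' reports as monitoring code 41.
#'
#' @param dir World directory.
#' @return A `knowledge_world`.
#' @export
load_world <- function(dir) {
  manifest_path <- file.path(dir, "world.json")
  for (f in c("world.json", "drugs.csv", "events.csv")) {
    if (!file.exists(file.path(dir, f))) {
      abort_not_found(sprintf("world component missing: %s (under %s)",
                              f, dir))
    }
  }
  raw <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  config <- do.call(world_config, as.list(
    raw$config[setdiff(names(raw$config),
                       c("planted_pub_lambda", "null_pub_lambda",
                         "joint_inflation", "planted_shared_prob"))]))
  drugs <- read_csv_chr(file.path(dir, "drugs.csv"))
  events <- read_csv_chr(file.path(dir, "events.csv"))
  planted <- read_csv_chr(file.path(dir, "planted.csv"))

  literature <- NULL
  lit_path <- file.path(dir, "literature.jsonl")
  if (file.exists(lit_path)) {
    lines <- readLines(lit_path, encoding = "UTF-8")
    records <- list()
    for (line in lines) {
      rec <- jsonlite::fromJSON(line, simplifyVector = FALSE)
      records[[rec$pmid]] <- data.frame(
        descriptor = vapply(rec$annotations, function(a)
          a$descriptor, character(1)),
        qualifier = vapply(rec$annotations, function(a)
          if (is.null(a$qualifier)) NA_character_ else a$qualifier,
          character(1)),
        stringsAsFactors = FALSE)
    }
    dmap <- read_csv_chr(file.path(dir, "drug_descriptors.csv"))
    emap <- read_csv_chr(file.path(dir, "event_descriptors.csv"))
    pa <- read_csv_chr(file.path(dir, "pharm_actions.csv"))
    literature <- literature_index(
      records,
      stats::setNames(dmap$descriptor, dmap$atc_code),
      stats::setNames(emap$descriptor, emap$event_code),
      split_to_sorted_list(pa$action, pa$descriptor))
  }

  corpus <- NULL
  cdir <- file.path(dir, "cooccurrence")
  if (dir.exists(cdir)) {
    term_files <- sort(list.files(cdir, pattern = "_terms\\.csv$"))
    corpus <- list()
    for (tf in term_files) {
      res <- sub("_terms\\.csv$", "", tf)
      terms <- read_csv_chr(file.path(cdir, tf), numeric_cols = "count")
      joint <- read_csv_chr(file.path(cdir, paste0(res, "_joint.csv")),
                            numeric_cols = "count")
      N <- as.numeric(readLines(file.path(cdir, paste0(res, "_total.txt")))[1])
      dsel <- terms$term_type == "drug"
      corpus[[res]] <- corpus_counts(
        res, N,
        stats::setNames(terms$count[dsel], terms$term[dsel]),
        stats::setNames(terms$count[!dsel], terms$term[!dsel]),
        joint)
    }
    if (!length(corpus)) corpus <- NULL
  }

  drug_profiles <- NULL; event_profiles <- NULL; pathway_map <- NULL
  tdir <- file.path(dir, "targets")
  if (file.exists(file.path(tdir, "drug_profiles.csv"))) {
    dp <- read_csv_chr(file.path(tdir, "drug_profiles.csv"))
    ep <- read_csv_chr(file.path(tdir, "event_profiles.csv"))
    drug_profiles <- split_to_sorted_list(dp$protein, dp$entity_id)
    event_profiles <- split_to_sorted_list(ep$protein, ep$entity_id)
    if (file.exists(file.path(tdir, "pathways.csv"))) {
      pw <- read_csv_chr(file.path(tdir, "pathways.csv"))
      pathway_map <- split_to_sorted_list(pw$pathway, pw$protein)
    }
  }

  structure(list(drugs = drugs, events = events, literature = literature,
                 corpus = corpus, drug_profiles = drug_profiles,
                 event_profiles = event_profiles, pathway_map = pathway_map,
                 planted = planted, config = config),
            class = "knowledge_world")
}
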