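# End-to-end orchestration: per-document extraction with forward-looking
# compound resolution, corpus-level blocklist construction, and the
# streaming pipeline over a corpus directory.

#' Pipeline configuration
#'
#' @param dialect Markup dialect of the corpus (`"xml-like"`, `"html-like"`,
#'   or `"auto"` to infer from the file extension).
#' @param lexicon Character vector of lexicon names, or a path to a one-name-
#'   per-line UTF-8 file.
#' @param blocklist A `tadf_blocklist`, or `NULL` to build one from the
#'   corpus at `threshold_fraction`.
#' @param allowlist Names exempt from all blocklisting rules.
#' @param threshold_fraction Blocklist document-count threshold as a fraction
#'   of the corpus size (default 7/1200).
#' @param classifier is_experimental classifier id or function.
#' @param smiles_backend SMILES backend id or function for the subsidiary
#'   output.
#' @param models Property models (default [default_property_models()]).
#' @return A `tadf_pipeline_config` list.
#' @export
pipeline_config <- function(dialect = "auto", lexicon = character(0),
                            blocklist = NULL, allowlist = character(0),
                            threshold_fraction = 7 / 1200,
                            classifier = "keyword",
                            smiles_backend = "lookup",
                            models = default_property_models()) {
  if (length(lexicon) == 1 && file.exists(lexicon)) {
    lexicon <- readLines(lexicon, encoding = "UTF-8", warn = FALSE)
  }
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1)
  structure(
    list(dialect = dialect, lexicon = lexicon, blocklist = blocklist,
         allowlist = allowlist, threshold_fraction = threshold_fraction,
         classifier = classifier, smiles_backend = smiles_backend,
         models = models),
    class = "tadf_pipeline_config"
  )
}

infer_dialect <- function(path, dialect) {
  if (dialect != "auto") return(dialect)
  if (stringr::str_ends(tolower(path), ".html")) "html-like" else "xml-like"
}

# Tag one paragraph element and return sentences with vetted CEM spans plus
# the raw (unvetted) spans for frequency counting.
tag_paragraph <- function(text, tagger, doc, blocklist, allowlist) {
  sentences <- segment_sentences(text)
  lapply(sentences, function(sent) {
    sent <- tag_cems(sent, tagger)
    raw_spans <- sent$cem_spans
    vetted <- Filter(function(span) {
      if (blocklist_contains(blocklist, span$name)) return(FALSE)
      following <- stringr::str_sub(sent$text, span$end + 1L)
      verdict <- apply_name_rules(span$name, doc = doc,
                                  following_text = following,
                                  allowlist = allowlist)
      verdict$verdict == "allow"
    }, raw_spans)
    sent$raw_spans <- raw_spans
    sent$cem_spans <- vetted
    sent
  })
}

#' Extract all property records from one document
#'
#' Runs the per-document stages in order: sentence segmentation and entity
#' tagging, abbreviation detection, sentence and table parsing,
#' forward-looking theme-compound resolution, and post-processing. The theme
#' registry is reset before returning, so repeated extraction of the same
#' document is reproducible and documents never share compound memory.
#'
#' @param doc A `tadf_document`.
#' @param config A `tadf_pipeline_config` (its blocklist is used as-is).
#' @return List with `records` (clean records with metadata attached) and
#'   `drops` (named drop counts).
#' @export
extract_document <- function(doc, config = pipeline_config()) {
  tagger <- lexicon_tagger(config$lexicon)
  registry <- new_theme_registry(doc$doc_id)
  on.exit(registry_reset(registry))
  candidates <- list()

  for (ei in seq_along(doc$elements)) {
    el <- doc$elements[[ei]]
    if (isTRUE(el$metadata)) next
    if (el$kind == "paragraph") {
      sentences <- tag_paragraph(el$text, tagger, doc, config$blocklist,
                                 config$allowlist)
      first_sentence <- if (length(sentences)) sentences[[1]]$text else ""
      for (si in seq_along(sentences)) {
        sent <- sentences[[si]]
        for (pair in detect_abbreviations(sent)) {
          if (is.null(registry$abbrev[[pair$short_form]])) {
            registry_add_abbreviation(registry, pair)
          }
        }
        for (span in sent$cem_spans) {
          registry_add(registry, span$name, "name", element_index = ei,
                       token_offset = sent$start + span$start)
        }
        for (model in config$models) {
          recs <- parse_sentence(
            sent, model,
            provenance = list(doc_id = doc$doc_id, element_index = ei,
                              sentence_index = si)
          )
          for (r in recs) {
            r$extra$section <- el$section
            r$extra$first_sentence <- first_sentence
            r$extra$sentence_text <- sent$text
            candidates[[length(candidates) + 1L]] <- r
          }
        }
      }
    } else if (el$kind == "table") {
      tab <- el$table
      comp_col <- find_compound_column(tab)
      if (!is.na(comp_col)) {
        for (ri in seq_along(tab$body)) {
          value <- tab$body[[ri]][[comp_col]]
          if (!nzchar(value)) next
          # table compound-column entries are auto-registered; only the hard
          # separator/DOI rules apply to them
          if (stringr::str_detect(value, stringr::fixed(CELL_SEPARATOR))) next
          type <- if (stringr::str_length(normalize_name(value)) <= 4) "label"
            else "name"
          registry_add(registry, value, type, element_index = ei, row = ri)
        }
      }
      recs <- parse_table(
        tab, config$models,
        provenance = list(doc_id = doc$doc_id, element_index = ei)
      )
      candidates <- c(candidates, recs)
    }
  }

  resolved <- list()
  for (r in candidates) {
    r2 <- resolve_compound(r, registry, doc)
    if (!is.null(r2)) resolved[[length(resolved) + 1L]] <- r2
  }
  post <- postprocess_records(resolved, doc, classifier = config$classifier)
  post$records <- lapply(post$records, function(r) {
    r$metadata <- doc$metadata
    r
  })
  post
}

#' Stream the chemical entity mentions of a corpus
#'
#' Tags every paragraph of every document and returns the raw (pre-blocklist)
#' mention stream used for frequency-table construction.
#'
#' @param paths Document file paths.
#' @param config A `tadf_pipeline_config`.
#' @return Data frame with columns `doc_id`, `name`.
#' @export
corpus_cem_stream <- function(paths, config = pipeline_config()) {
  tagger <- lexicon_tagger(config$lexicon)
  out <- list()
  for (p in paths) {
    doc <- tryCatch(read_document(p, infer_dialect(p, config$dialect)),
                    error = function(e) NULL)
    if (is.null(doc)) next
    for (el in doc_elements(doc)) {
      if (el$kind != "paragraph") next
      for (sent in segment_sentences(el$text)) {
        sent <- tag_cems(sent, tagger)
        for (span in sent$cem_spans) {
          out[[length(out) + 1L]] <- data.frame(
            doc_id = doc$doc_id, name = span$name, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(doc_id = character(0), name = character(0)))
  }
  do.call(rbind, out)
}

#' Run the full extraction pipeline over a corpus directory
#'
#' Per document: read, segment and tag, detect abbreviations, parse sentences
#' and tables, resolve theme compounds (registry reset after each document),
#' post-process; finally the subsidiary SMILES output is derived from the
#' master records. When the configuration carries no blocklist, one is built
#' first from the corpus mention stream at `threshold_fraction`. Unreadable
#' documents are logged and skipped.
#'
#' @param corpus_dir Directory containing the documents (either directly or
#'   under `docs/`).
#' @param config A `tadf_pipeline_config`.
#' @param smiles Also build the subsidiary SMILES record set.
#' @return List with `records`, `subsidiary`, `blocklist` and `report`
#'   (per-document record counts and drop reasons).
#' @export
run_pipeline <- function(corpus_dir, config = pipeline_config(), smiles = TRUE) {
  doc_dir <- if (dir.exists(file.path(corpus_dir, "docs"))) {
    file.path(corpus_dir, "docs")
  } else corpus_dir
  paths <- sort(list.files(doc_dir, pattern = "\\.(xml|html)$",
                           full.names = TRUE))

  blocklist <- config$blocklist
  if (is.null(blocklist) && length(paths)) {
    freq <- build_frequency_table(corpus_cem_stream(paths, config))
    blocklist <- withCallingHandlers(
      build_blocklist(freq, config$threshold_fraction),
      warning = function(w) {
        message("blocklist: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    config$blocklist <- blocklist
  }

  records <- list()
  report <- list(documents = list(), drops = integer(0))
  for (p in paths) {
    res <- tryCatch(
      {
        doc <- read_document(p, infer_dialect(p, config$dialect))
        extract_document(doc, config)
      },
      error = function(e) {
        message("skipping unreadable document ", p, ": ", conditionMessage(e))
        NULL
      }
    )
    if (is.null(res)) next
    records <- c(records, res$records)
    report$documents[[basename(p)]] <- list(
      n_records = length(res$records), drops = res$drops
    )
    for (reason in names(res$drops)) {
      cur <- if (reason %in% names(report$drops)) report$drops[[reason]] else 0L
      report$drops[reason] <- cur + res$drops[[reason]]
    }
  }

  subsidiary <- if (smiles) {
    attach_smiles(records, backend = config$smiles_backend)
  } else list()
  list(records = records, subsidiary = subsidiary, blocklist = blocklist,
       report = report)
}
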