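# Corpus-level blocklist of ubiquitous chemical entity mentions, name/label
# blocklisting rules, and document-scoped forward-looking compound resolution.

#' Build a CEM occurrence-frequency table
#'
#' Counts, for each normalized chemical entity mention, the number of distinct
#' documents that contain it; multiple occurrences within the same document
#' count once.
#'
#' @param cem_stream Data frame with columns `doc_id` and `name`.
#' @return A `tadf_frequency_table`: list with `counts` (named integer
#'   vector) and `n_documents`.
#' @export
build_frequency_table <- function(cem_stream) {
  stopifnot(is.data.frame(cem_stream), all(c("doc_id", "name") %in% names(cem_stream)))
  if (nrow(cem_stream) == 0) {
    return(structure(list(counts = integer(0), n_documents = 0L),
                     class = "tadf_frequency_table"))
  }
  cem_stream$name <- normalize_name(cem_stream$name)
  dedup <- unique(cem_stream[, c("doc_id", "name")])
  counts <- table(dedup$name)
  structure(
    list(counts = setNames(as.integer(counts), names(counts)),
         n_documents = length(unique(cem_stream$doc_id))),
    class = "tadf_frequency_table"
  )
}

#' Build a blocklist from a frequency table
#'
#' Blocklists every name whose document count reaches
#' `ceiling(threshold_fraction * n_documents)`. The default fraction 7/1200
#' reproduces the absolute cut-off of seven documents on a 1200-document
#' corpus while scaling sensibly to smaller corpora. An enrichment hook adds
#' case and whitespace variants of listed entries. When the scaled cut-off
#' falls below 2 every name would be blocklisted; a warning is emitted.
#'
#' @param freq A `tadf_frequency_table`.
#' @param threshold_fraction Fraction of documents (in `(0, 1]`).
#' @param extra Manually blocklisted names.
#' @return A `tadf_blocklist`: list with `entries`, `threshold_fraction`,
#'   `provenance` (named character: "frequency", "rule" or "manual").
#' @export
build_blocklist <- function(freq, threshold_fraction = 7 / 1200,
                            extra = character(0)) {
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1)
  cutoff <- ceiling(threshold_fraction * freq$n_documents)
  if (freq$n_documents > 0 && cutoff < 2) {
    warning("blocklist cut-off below 2 for a ", freq$n_documents,
            "-document corpus; every recurring name will be blocklisted")
  }
  base <- names(freq$counts)[freq$counts >= cutoff]
  prov <- setNames(rep("frequency", length(base)), base)
  if (length(extra)) {
    extra <- normalize_name(extra)
    prov[setdiff(extra, names(prov))] <- "manual"
  }
  entries <- names(prov)
  # enrichment: case and whitespace/hyphenation variants
  variants <- unique(c(tolower(entries), toupper(entries),
                       stringr::str_replace_all(entries, "-", " "),
                       stringr::str_replace_all(entries, " ", "-")))
  variants <- setdiff(normalize_name(variants), entries)
  prov[variants] <- "rule"
  structure(
    list(entries = names(prov), threshold_fraction = threshold_fraction,
         provenance = prov),
    class = "tadf_blocklist"
  )
}

#' @export
print.tadf_blocklist <- function(x, ...) {
  cat("<tadf_blocklist>", length(x$entries), "entries, threshold",
      format(x$threshold_fraction, digits = 4), "\n")
  invisible(x)
}

blocklist_contains <- function(blocklist, name) {
  if (is.null(blocklist)) return(FALSE)
  normalize_name(name) %in% blocklist$entries ||
    tolower(normalize_name(name)) %in% tolower(blocklist$entries)
}

# configuration for the humanly compiled rules
default_rule_config <- function() {
  list(
    name_affixes = c("-based", "-containing", "-type"),
    follow_words = c("-based", "based", "part", "segment"),
    name_suffixes = c("o", "yl", "oxy"),
    electronic_states = as.vector(outer(c("S", "T"), 0:9, paste0)),
    unit_strings = c("nm", "eV", "meV", "μs", "ns", "ms", "ps", "s", "K",
                     "%", "kJ/mol", "cd", "Hz", "V", "mW", "mA"),
    month_names = c("January", "February", "March", "April", "May", "June",
                    "July", "August", "September", "October", "November",
                    "December")
  )
}

#' Apply name blocklisting rules to a candidate compound name
#'
#' Blocks names containing the cell separator, names containing the current
#' document's DOI, names carrying (or followed in text by) "-based"/"part"/
#' "segment"-style morphology, and names ending in substituent-fragment
#' suffixes ("o" as in amino, "yl" as in phenyl, and configured alike
#' endings). An allowlist entry overrides every block.
#'
#' @param name Normalized candidate name.
#' @param doc Optional `tadf_document` (for the DOI rule).
#' @param following_text Text immediately following the mention, if known.
#' @param allowlist Character vector of names exempt from all rules.
#' @param config Rule configuration (see `default_rule_config`).
#' @return List `(verdict = "allow"|"block", reason = NULL|string)`.
#' @export
apply_name_rules <- function(name, doc = NULL, following_text = "",
                             allowlist = character(0),
                             config = default_rule_config()) {
  name <- normalize_name(name)
  allow <- list(verdict = "allow", reason = NULL)
  if (name %in% normalize_name(allowlist)) return(allow)
  block <- function(reason) list(verdict = "block", reason = reason)

  if (stringr::str_detect(name, stringr::fixed(CELL_SEPARATOR))) {
    return(block("contains cell separator"))
  }
  doi <- doc$metadata$doi %||% NULL
  if (!is.null(doi) && nzchar(doi) &&
      stringr::str_detect(name, stringr::fixed(doi))) {
    return(block("contains document DOI"))
  }
  for (affix in config$name_affixes) {
    if (stringr::str_ends(name, stringr::fixed(affix))) {
      return(block(paste0("name carries '", affix, "' morphology")))
    }
  }
  if (nzchar(following_text)) {
    next_word <- stringr::str_match(
      following_text, "^\\s*(-?[A-Za-z]+)"
    )[1, 2]
    if (!is.na(next_word) && tolower(next_word) %in% tolower(config$follow_words)) {
      return(block(paste0("followed by '", next_word, "'")))
    }
  }
  for (suf in config$name_suffixes) {
    if (stringr::str_ends(tolower(name), suf)) {
      return(block(paste0("fragment suffix '", suf, "'")))
    }
  }
  allow
}

#' Apply label blocklisting rules to a candidate compound label
#'
#' Blocks date strings, electronic-state symbols (S0, S1, T1, ...), unit
#' strings, numbers followed by `%` or `wt %`, and strings longer than 4
#' characters.
#'
#' @param label Candidate label.
#' @param config Rule configuration.
#' @return List `(verdict, reason)` as in [apply_name_rules()].
#' @export
apply_label_rules <- function(label, config = default_rule_config()) {
  label <- stringr::str_trim(label)
  block <- function(reason) list(verdict = "block", reason = reason)
  if (stringr::str_length(label) > 4) return(block("longer than 4 characters"))
  if (stringr::str_detect(label, "^[0-9]{4}-[0-9]{2}-[0-9]{2}$")) {
    return(block("date string"))
  }
  month_re <- paste0("^(?:", paste(config$month_names, collapse = "|"),
                     ")\\s+[0-9]{4}$")
  if (stringr::str_detect(label, month_re)) return(block("date string"))
  if (label %in% config$electronic_states) return(block("electronic state"))
  if (canonical_unicode(label) %in% config$unit_strings) return(block("unit string"))
  if (stringr::str_detect(label, "^[0-9]+(?:\\.[0-9]+)?\\s*(?:wt\\s*)?%$")) {
    return(block("number with percent"))
  }
  list(verdict = "allow", reason = NULL)
}

# ---- forward-looking theme registry -----------------------------------------

#' Create a document-scoped ThemeCompound registry
#'
#' The registry remembers names and labels of focal compounds as they are
#' detected while scanning a document, together with their positions, so that
#' later records lacking a compound can be resolved to the nearest theme
#' compound. It is never shared across documents and must be reset when a
#' document's extraction concludes.
#'
#' @param doc_id Document id the registry is scoped to.
#' @return A `tadf_theme_registry` (environment).
#' @export
new_theme_registry <- function(doc_id) {
  reg <- new.env(parent = emptyenv())
  reg$doc_id <- doc_id
  reg$entries <- list()   # list of (value, type, element_index, token_offset, row)
  reg$abbrev <- list()    # short_form -> long_form
  class(reg) <- "tadf_theme_registry"
  reg
}

#' Register a theme compound name or label
#'
#' @param registry A `tadf_theme_registry`.
#' @param value Normalized name or label.
#' @param type `"name"` or `"label"`.
#' @param element_index Index of the element in the document.
#' @param token_offset Token position of the mention inside the element.
#' @param row Table row for entries registered from a compound column.
#' @export
registry_add <- function(registry, value, type = c("name", "label"),
                         element_index, token_offset = 0L, row = NA_integer_) {
  type <- match.arg(type)
  value <- if (type == "name") normalize_name(value) else stringr::str_trim(value)
  if (!nzchar(value)) return(invisible(registry))
  registry$entries[[length(registry$entries) + 1L]] <- list(
    value = value, type = type, element_index = element_index,
    token_offset = token_offset, row = row
  )
  invisible(registry)
}

#' Register an abbreviation pair for document-wide name unification
#' @param registry A `tadf_theme_registry`.
#' @param pair An abbreviation pair from [detect_abbreviations()].
#' @export
registry_add_abbreviation <- function(registry, pair) {
  registry$abbrev[[pair$short_form]] <- pair$long_form
  invisible(registry)
}

#' Reset a theme registry (document-extraction conclusion contract)
#' @param registry A `tadf_theme_registry`.
#' @export
registry_reset <- function(registry) {
  registry$entries <- list()
  registry$abbrev <- list()
  invisible(registry)
}

# Expand a compound with both sides of any known abbreviation pair.
unify_abbreviations <- function(compound, registry) {
  if (is.null(compound)) return(NULL)
  names <- compound$names
  extra <- character(0)
  for (short in names(registry$abbrev)) {
    long <- registry$abbrev[[short]]
    if (short %in% names || any(tolower(names) == tolower(long))) {
      extra <- c(extra, short, long)
    }
  }
  compound$names <- unique(c(names, normalize_name(extra)))
  compound
}

#' Resolve the compound of a candidate record
#'
#' A record that already carries a compound keeps it (with abbreviation
#' unification). A record without a compound is attached to the registered
#' theme compound nearest by token distance within the same element (same
#' paragraph, or same table row first); ties break toward the preceding
#' mention. Records that still lack a compound and whose element contains no
#' theme compound are dropped (`NULL`).
#'
#' @param record A `tadf_candidate`.
#' @param registry A populated `tadf_theme_registry`.
#' @param doc The `tadf_document` (unused by the default metric; kept for
#'   rule extensions).
#' @return The resolved record, or `NULL` when the record must be dropped.
#' @export
resolve_compound <- function(record, registry, doc = NULL) {
  if (!is.null(record$compound) &&
      (length(record$compound$names) || length(record$compound$labels))) {
    record$compound <- unify_abbreviations(record$compound, registry)
    return(record)
  }
  el <- record$provenance$element_index
  same_el <- Filter(function(e) identical(e$element_index, el), registry$entries)
  if (!length(same_el)) return(NULL)

  # table records: prefer an entry registered on the same row
  row <- if (!is.null(record$provenance$cell)) {
    record$provenance$cell[["row"]]
  } else NA_integer_
  if (!is.na(row)) {
    same_row <- Filter(function(e) identical(e$row, as.integer(row)), same_el)
    if (length(same_row)) same_el <- same_row
  }

  off <- record$provenance$specifier_offset %||% record$provenance$token_offset %||% 0L
  d <- vapply(same_el, function(e) abs(e$token_offset - off), numeric(1))
  pref <- vapply(same_el, function(e) e$token_offset <= off, logical(1))
  best <- same_el[[order(d, !pref)[1]]]
  record$compound <- if (best$type == "name") new_compound(names = best$value)
    else new_compound(labels = best$value)
  record$compound <- unify_abbreviations(record$compound, registry)
  record
}
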