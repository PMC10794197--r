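# Sentence template parsing and table-cell parsing, including the three
# special table parsers (combined E_S/E_T/ΔE_ST columns, fractional PLQY,
# shared lifetime cells).

#' Cell/header separator used for table serialization
#'
#' Table cells are concatenated with their column headers into a
#' sentence-like string using this separator (U+1F643 repeated four times).
#' The same string is also a hard blocklisting pattern for compound names.
#' @export
CELL_SEPARATOR <- strrep("\U0001F643", 4)

new_candidate <- function(property_id, quantity, standard_value, parser,
                          compound = NULL, extra = list(),
                          provenance = list()) {
  provenance$parser <- parser
  structure(
    list(
      property_id = property_id,
      quantity = quantity,
      standard_value = standard_value,
      compound = compound,
      extra = extra,
      provenance = provenance
    ),
    class = "tadf_candidate"
  )
}

new_compound <- function(names = character(0), labels = character(0)) {
  list(names = unique(normalize_name(names)), labels = unique(labels))
}

# ---- sentence parsing --------------------------------------------------------

.temp_explicit_re <- "\\bat\\s+([0-9]+(?:\\.[0-9]+)?)\\s*K(?![A-Za-z])"
.temp_room_re <- "(?i)\\b(?:at\\s+)?(?:room[ -]temperature|r\\.t\\.|RT)\\b"

#' Parse a tagged sentence against one property model
#'
#' Matches the finite template set: specifier--(of compound)--link
#' words--quantity, with the compound attached from an of-phrase, the subject
#' position, or the nearest tagged chemical entity mention. Temperature
#' phrases ("at 77 K", "at room temperature") are captured into the record's
#' extra fields.
#'
#' @param sentence A `tadf_sentence` with `cem_spans` populated.
#' @param model A `tadf_property_model`.
#' @param provenance List with at least `doc_id`, `element_index`,
#'   `sentence_index`.
#' @return List of `tadf_candidate` records (possibly empty).
#' @export
parse_sentence <- function(sentence, model, provenance = list()) {
  text <- canonical_unicode(sentence$text)
  ex <- model$compiled %||% compile_parse_expressions(model)
  spec_locs <- stringr::str_locate_all(
    text, paste0("(?<![\\p{L}\\p{Greek}])", ex$specifier_re)
  )[[1]]
  if (nrow(spec_locs) == 0) return(list())

  records <- list()
  for (i in seq_len(nrow(spec_locs))) {
    s_start <- spec_locs[i, 1]; s_end <- spec_locs[i, 2]
    after <- stringr::str_sub(text, s_end + 1L)
    lm <- stringr::str_match(after, paste0("^", .link_re))
    if (is.na(lm[1, 1])) next
    adv <- stringr::str_length(lm[1, 1])
    pos0 <- s_end + adv               # 0-based offset where the next token starts
    compound_of <- NULL
    span_here <- Find(function(s) s$start == pos0, sentence$cem_spans)
    if (!is.null(span_here)) {
      compound_of <- span_here$name
      rest <- stringr::str_sub(text, span_here$end + 1L)
      lm2 <- stringr::str_match(rest, paste0("^", .link_re))
      if (is.na(lm2[1, 1])) next
      q <- parse_quantity(
        stringr::str_sub(rest, stringr::str_length(lm2[1, 1]) + 1L),
        model, anchored = TRUE
      )
    } else {
      q <- parse_quantity(stringr::str_sub(after, adv + 1L), model, anchored = TRUE)
    }
    if (is.null(q)) next

    compound <- NULL
    if (!is.null(compound_of)) {
      compound <- new_compound(names = compound_of)
    } else if (length(sentence$cem_spans)) {
      # nearest CEM to the specifier, ties broken toward the preceding one
      d <- vapply(sentence$cem_spans, function(s) {
        if (s$end <= s_start - 1L) s_start - 1L - s$end else s$start - s_end
      }, numeric(1))
      pref <- vapply(sentence$cem_spans, function(s) s$end <= s_start - 1L, logical(1))
      best <- order(d, !pref)[1]
      compound <- new_compound(names = sentence$cem_spans[[best]]$name)
    }

    extra <- list()
    tm <- stringr::str_match(text, .temp_explicit_re)
    if (!is.na(tm[1, 1])) extra$temperature <- as.numeric(tm[1, 2])
    if (stringr::str_detect(text, .temp_room_re)) extra$room_temperature <- TRUE

    prov <- provenance
    # element-level character offset of the specifier (sentence start + local)
    prov$specifier_offset <- (sentence$start %||% 0L) + s_start - 1L
    records[[length(records) + 1L]] <- new_candidate(
      property_id = model$property_id, quantity = q,
      standard_value = to_standard(q, model), parser = "sentence",
      compound = compound, extra = extra, provenance = prov
    )
  }
  dedup_candidates(records)
}

.link_re <- paste0(
  "(?:\\s*(?:(?:is|was|were|of|at|in|measured to be|found to be|",
  "estimated to be|determined to be|to be|as high as|as low as|reaches|",
  "reached|amounts to|about|approximately|around|up to)(?=\\s|$)|[=:~]))+\\s*"
)

dedup_candidates <- function(records) {
  if (length(records) <= 1) return(records)
  keys <- vapply(records, function(r) {
    paste(r$property_id, paste(r$quantity$values, collapse = ","),
          r$quantity$unit,
          paste(r$provenance$element_index, r$provenance$sentence_index))
  }, character(1))
  records[!duplicated(keys)]
}

# ---- table serialization and generic cell parsing ---------------------------

#' Serialize a table cell with its headers
#'
#' Joins the cell's column headers (outermost first) and the cell text with
#' [CELL_SEPARATOR] into a sentence-like string; the number of segments is
#' the number of header levels for that column plus one.
#'
#' @param table A `tadf_table`.
#' @param row,col 1-based body row and column indices.
#' @return The serialized string.
#' @export
serialize_cell <- function(table, row, col) {
  if (row < 1 || row > length(table$body) || col < 1 || col > table$ncol) {
    stop("cell index out of range: (", row, ",", col, ")")
  }
  paste(c(table$column_headers[[col]], table$body[[row]][[col]]),
        collapse = CELL_SEPARATOR)
}

split_cell_string <- function(cell_string) {
  segs <- stringr::str_split(cell_string, stringr::fixed(CELL_SEPARATOR))[[1]]
  list(headers = head(segs, -1), cell = tail(segs, 1))
}

header_unit <- function(headers, model) {
  for (h in rev(canonical_unicode(headers))) {
    m <- stringr::str_match_all(h, "\\(([^)]*)\\)")[[1]]
    for (inner in m[, 2]) {
      inner <- stringr::str_trim(inner)
      if (inner %in% names(model$allowed_units)) return(inner)
    }
  }
  # a bare % in a header also declares the unit for fractions
  if (model$standard_unit == "%" &&
      any(stringr::str_detect(headers, stringr::fixed("%")))) return("%")
  NULL
}

header_has_specifier <- function(headers, model) {
  ex <- model$compiled %||% compile_parse_expressions(model)
  any(stringr::str_detect(
    canonical_unicode(headers),
    paste0("(?<![\\p{L}\\p{Greek}])", ex$specifier_re)
  ))
}

#' Parse a serialized table cell against one property model
#'
#' The specifier is sought among the header segments; the unit is taken from
#' the header when declared there (in parentheses), otherwise from the cell;
#' the first compatible number wins (first-come-first-served). The compound
#' comes from the row's compound column when supplied.
#'
#' @param cell_string String produced by [serialize_cell()].
#' @param model A `tadf_property_model`.
#' @param row_compound Optional compound (a names/labels list or a string).
#' @param provenance Provenance list.
#' @return List of `tadf_candidate` (zero or one).
#' @export
parse_cell <- function(cell_string, model, row_compound = NULL,
                       provenance = list()) {
  parts <- split_cell_string(cell_string)
  if (!length(parts$headers) || !nzchar(parts$cell)) return(list())
  if (!header_has_specifier(parts$headers, model)) return(list())

  h_unit <- header_unit(parts$headers, model)
  cell <- canonical_unicode(parts$cell)
  if (!is.null(h_unit)) {
    q <- parse_quantity(cell, model, require_unit = FALSE)
    if (is.null(q)) return(list())
    if (!nzchar(q$unit)) q$unit <- h_unit
  } else {
    q <- parse_quantity(cell, model, require_unit = TRUE)
    if (is.null(q)) return(list())
  }
  compound <- coerce_compound(row_compound)
  list(new_candidate(
    property_id = model$property_id, quantity = q,
    standard_value = to_standard(q, model), parser = "table_cell",
    compound = compound, provenance = provenance
  ))
}

coerce_compound <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) {
    x <- normalize_name(x)
    if (!nzchar(x)) return(NULL)
    if (stringr::str_length(x) <= 4) new_compound(labels = x)
    else new_compound(names = x)
  } else x
}

# ---- special table parsers ---------------------------------------------------

.slash_sep_re <- "\\s*[/;]\\s*"

strip_parenthetical <- function(x) {
  stringr::str_trim(stringr::str_remove_all(x, "\\([^)]*\\)"))
}

find_sep <- function(header_core) {
  if (stringr::str_detect(header_core, "/")) "/" else
    if (stringr::str_detect(header_core, ";") ) ";" else NULL
}

combined_est_header_slots <- function(headers) {
  # innermost header with an E_S / E_T / ΔE_ST slash pattern
  for (h in rev(canonical_unicode(headers))) {
    core <- strip_parenthetical(h)
    sep <- find_sep(core)
    if (is.null(sep)) next
    slots <- stringr::str_trim(stringr::str_split(core, stringr::fixed(sep))[[1]])
    est_idx <- which(stringr::str_detect(slots, "^ΔE"))
    if (length(est_idx) != 1) next
    es_idx <- which(stringr::str_detect(slots, "^E\\s*_?S[0-9]?$"))
    et_idx <- which(stringr::str_detect(slots, "^E\\s*_?T[0-9]?$"))
    if (length(es_idx) && length(et_idx)) {
      return(list(header = h, sep = sep, n = length(slots),
                  est = est_idx, es = es_idx[1], et = et_idx[1]))
    }
  }
  NULL
}

#' Parse a combined E_S/E_T/ΔE_ST table cell
#'
#' Handles singlet-triplet splittings reported in the same column as singlet
#' and triplet energies under a header such as `ES/ET/ΔEST (eV)`. The cell is
#' split on the header's own separator and the field positionally aligned
#' with the splitting slot is emitted; when the singlet and triplet energies
#' are also numeric, an inconsistency |E_S - E_T - ΔE_ST| > 0.05 eV raises a
#' consistency-warning flag on the record.
#'
#' @inheritParams parse_cell
#' @return List of `tadf_candidate` (zero or one).
#' @export
parse_combined_est_cell <- function(cell_string, model = NULL,
                                    row_compound = NULL, provenance = list()) {
  models <- default_property_models()
  model <- model %||% models$delta_e_st
  parts <- split_cell_string(cell_string)
  slots <- combined_est_header_slots(parts$headers)
  if (is.null(slots)) return(list())
  unit <- header_unit(parts$headers, model) %||% "eV"

  fields <- stringr::str_trim(
    stringr::str_split(canonical_unicode(parts$cell), stringr::fixed(slots$sep))[[1]]
  )
  if (length(fields) != slots$n) return(list())
  val <- suppressWarnings(as.numeric(fields[[slots$est]]))
  if (is.na(val)) return(list())

  q <- structure(list(values = val, unit = unit, raw_text = parts$cell),
                 class = "tadf_quantity")
  extra <- list()
  es <- suppressWarnings(as.numeric(fields[[slots$es]]))
  et <- suppressWarnings(as.numeric(fields[[slots$et]]))
  if (!is.na(es) && !is.na(et)) {
    std <- to_standard(q, model)
    es_std <- es * model$allowed_units[[unit]]
    et_std <- et * model$allowed_units[[unit]]
    if (abs(es_std - et_std - std) > 0.05) extra$consistency_warning <- TRUE
  }
  list(new_candidate(
    property_id = "delta_e_st", quantity = q,
    standard_value = to_standard(q, model), parser = "combined_est",
    compound = coerce_compound(row_compound), extra = extra,
    provenance = provenance
  ))
}

claims_combined_est <- function(cell_string) {
  !is.null(combined_est_header_slots(split_cell_string(cell_string)$headers))
}

shared_lifetime_header_slots <- function(headers, models) {
  taud_re <- paste0("(?<![\\p{L}\\p{Greek}])",
                    (models$tau_d$compiled %||% compile_parse_expressions(models$tau_d))$specifier_re)
  other_res <- c(
    paste0("(?<![\\p{L}\\p{Greek}])",
           (models$lambda_em$compiled %||% compile_parse_expressions(models$lambda_em))$specifier_re),
    paste0("(?<![\\p{L}\\p{Greek}])",
           (models$plqy$compiled %||% compile_parse_expressions(models$plqy))$specifier_re),
    "(?<![\\p{L}\\p{Greek}])τ\\s*p|(?<![\\p{L}\\p{Greek}])τprompt|prompt lifetime"
  )
  for (h in rev(canonical_unicode(headers))) {
    core <- strip_parenthetical(h)
    sep <- find_sep(core)
    if (is.null(sep)) next
    slots <- stringr::str_trim(stringr::str_split(core, stringr::fixed(sep))[[1]])
    taud_idx <- which(stringr::str_detect(slots, taud_re))
    if (length(taud_idx) != 1) next
    others <- setdiff(seq_along(slots), taud_idx)
    other_ok <- vapply(slots[others], function(s) {
      any(vapply(other_res, function(re) stringr::str_detect(s, re), logical(1)))
    }, logical(1))
    if (length(others) && all(other_ok)) {
      # per-slot units from the header parenthetical, aligned by separator
      units <- NULL
      um <- stringr::str_match(h, "\\(([^)]*)\\)")
      if (!is.na(um[1, 2])) {
        units <- stringr::str_trim(
          stringr::str_split(canonical_unicode(um[1, 2]), stringr::fixed(sep))[[1]]
        )
      }
      return(list(header = h, sep = sep, n = length(slots), taud = taud_idx,
                  units = units))
    }
  }
  NULL
}

#' Parse a shared-lifetime table cell
#'
#' Handles delayed lifetimes reported in the same table cell as the prompt
#' lifetime, emission wavelength or quantum yield (header e.g.
#' `τp/τd (ns/μs)`). Header fields are positionally aligned with cell fields
#' using the header's separator; only the delayed-lifetime slot is emitted,
#' with its per-slot header unit (a single declared unit applies to all
#' slots).
#'
#' @inheritParams parse_cell
#' @return List of `tadf_candidate` (zero or one).
#' @export
parse_shared_lifetime_cell <- function(cell_string, model = NULL,
                                       row_compound = NULL, provenance = list()) {
  models <- default_property_models()
  model <- model %||% models$tau_d
  parts <- split_cell_string(cell_string)
  slots <- shared_lifetime_header_slots(parts$headers, models)
  if (is.null(slots)) return(list())

  fields <- stringr::str_trim(
    stringr::str_split(canonical_unicode(parts$cell), stringr::fixed(slots$sep))[[1]]
  )
  if (length(fields) != slots$n) return(list())
  val <- suppressWarnings(as.numeric(fields[[slots$taud]]))
  if (is.na(val)) return(list())

  unit <- if (!is.null(slots$units)) {
    if (length(slots$units) == slots$n) slots$units[[slots$taud]]
    else slots$units[[1]]
  } else model$standard_unit
  if (!unit %in% names(model$allowed_units)) return(list())

  q <- structure(list(values = val, unit = unit, raw_text = parts$cell),
                 class = "tadf_quantity")
  list(new_candidate(
    property_id = "tau_d", quantity = q,
    standard_value = to_standard(q, model), parser = "shared_lifetime",
    compound = coerce_compound(row_compound), provenance = provenance
  ))
}

claims_shared_lifetime <- function(cell_string) {
  !is.null(shared_lifetime_header_slots(
    split_cell_string(cell_string)$headers, default_property_models()
  ))
}

#' Parse a fractional PLQY table cell
#'
#' Quantum yields are sometimes tabulated as fractions in `[0, 1]` with no
#' percent sign anywhere in the header or cell; such values are emitted with
#' standard value `v * 100` %. Cells with a percent sign defer to
#' [parse_cell()].
#'
#' @inheritParams parse_cell
#' @return List of `tadf_candidate` (zero or one).
#' @export
parse_fractional_plqy_cell <- function(cell_string, model = NULL,
                                       row_compound = NULL, provenance = list()) {
  models <- default_property_models()
  model <- model %||% models$plqy
  parts <- split_cell_string(cell_string)
  if (!header_has_specifier(parts$headers, model)) return(list())
  if (any(stringr::str_detect(c(parts$headers, parts$cell), stringr::fixed("%")))) {
    return(list())
  }
  val <- suppressWarnings(as.numeric(stringr::str_trim(parts$cell)))
  if (is.na(val) || val < 0 || val > 1) return(list())
  q <- structure(list(values = val, unit = "", raw_text = parts$cell),
                 class = "tadf_quantity")
  list(new_candidate(
    property_id = "plqy", quantity = q, standard_value = val * 100,
    parser = "fractional_plqy", compound = coerce_compound(row_compound),
    provenance = provenance
  ))
}

claims_fractional_plqy <- function(cell_string, model = NULL) {
  model <- model %||% default_property_models()$plqy
  parts <- split_cell_string(cell_string)
  if (!header_has_specifier(parts$headers, model)) return(FALSE)
  if (any(stringr::str_detect(c(parts$headers, parts$cell), stringr::fixed("%")))) {
    return(FALSE)
  }
  val <- suppressWarnings(as.numeric(stringr::str_trim(parts$cell)))
  !is.na(val) && val >= 0 && val <= 1
}

# ---- table dispatch ----------------------------------------------------------

.compound_column_headers <- c(
  "compound", "compounds", "emitter", "emitters", "molecule", "molecules",
  "material", "materials", "dye", "dyes"
)

#' Find the compound column of a table
#'
#' @param table A `tadf_table`.
#' @return Column index or `NA` when the table declares no compound column.
#' @export
find_compound_column <- function(table) {
  for (j in seq_len(table$ncol)) {
    hs <- tolower(table$column_headers[[j]])
    if (any(hs %in% .compound_column_headers)) return(j)
  }
  NA_integer_
}

#' Parse every cell of a table through the ordered parser list
#'
#' Dispatch is first-match over combined E_S/E_T/ΔE_ST, shared lifetime,
#' fractional PLQY, then the generic cell parser for every property model;
#' special parsers claim their header patterns exclusively so a cell never
#' double-emits for the same property.
#'
#' @param table A `tadf_table`.
#' @param models List of property models.
#' @param provenance Provenance list (doc_id, element_index).
#' @return List of `tadf_candidate`.
#' @export
parse_table <- function(table, models = default_property_models(),
                        provenance = list()) {
  records <- list()
  comp_col <- find_compound_column(table)
  for (i in seq_along(table$body)) {
    row_compound <- if (!is.na(comp_col)) table$body[[i]][[comp_col]] else NULL
    for (j in seq_len(table$ncol)) {
      if (!is.na(comp_col) && j == comp_col) next
      cs <- serialize_cell(table, i, j)
      prov <- provenance
      prov$cell <- c(row = i, col = j)
      cell_records <-
        if (claims_combined_est(cs)) {
          parse_combined_est_cell(cs, models$delta_e_st, row_compound, prov)
        } else if (claims_shared_lifetime(cs)) {
          parse_shared_lifetime_cell(cs, models$tau_d, row_compound, prov)
        } else if (claims_fractional_plqy(cs, models$plqy)) {
          parse_fractional_plqy_cell(cs, models$plqy, row_compound, prov)
        } else {
          unlist(lapply(models, function(m) {
            parse_cell(cs, m, row_compound, prov)
          }), recursive = FALSE)
        }
      records <- c(records, cell_records)
    }
  }
  records
}
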