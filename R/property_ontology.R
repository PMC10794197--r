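# Property ontologies for the four target photophysical quantities and the
# quantity grammar (numbers, ranges, scientific notation, unit conversion).

#' Default property models
#'
#' Builds the four property ontologies: maximum emission wavelength
#' (`lambda_em`, standard unit nm), photoluminescence quantum yield (`plqy`,
#' standard unit %), singlet-triplet energy splitting (`delta_e_st`, standard
#' unit eV) and delayed fluorescence lifetime (`tau_d`, standard unit μs).
#' Specifier lists and allowed units are configuration, loaded from the YAML
#' file shipped with the package; pass `config` to override.
#'
#' @param config Path to a YAML property-model config (default: packaged one).
#' @return Named list of `tadf_property_model` objects keyed by property id.
#' @export
default_property_models <- function(config = NULL) {
  use_cache <- is.null(config)
  if (use_cache && !is.null(.ontology_cache$models)) return(.ontology_cache$models)
  if (is.null(config)) {
    config <- system.file("extdata", "property_models.yaml", package = "tadfminer")
  }
  cfg <- yaml::read_yaml(config)
  models <- lapply(names(cfg), function(id) {
    m <- cfg[[id]]
    units <- vapply(m$allowed_units, function(u) {
      if (!is.null(u$factor_inverse)) 1 / u$factor_inverse else u$factor
    }, numeric(1))
    names(units) <- vapply(m$allowed_units, function(u) u$symbol, character(1))
    stopifnot(all(units > 0), length(m$specifiers) > 0)
    structure(
      list(
        property_id = id,
        specifiers = canonical_unicode(unlist(m$specifiers)),
        dimension = m$dimension,
        allowed_units = units,
        standard_unit = m$standard_unit,
        extra_fields = unlist(m$extra_fields %||% character(0))
      ),
      class = "tadf_property_model"
    )
  })
  models <- lapply(models, function(m) {
    m$compiled <- compile_parse_expressions(m)
    m
  })
  names(models) <- names(cfg)
  if (use_cache) .ontology_cache$models <- models
  models
}

.ontology_cache <- new.env(parent = emptyenv())

.number_re <- "[-+]?[0-9]+(?:\\.[0-9]+)?(?:\\s*x\\s*10\\^?[-+]?[0-9]+|[eE][-+]?[0-9]+)?"
.range_sep_re <- "\\s*(?:–|—|-|to)\\s*"

unit_alternation <- function(model) {
  syms <- names(model$allowed_units)
  syms <- syms[order(-stringr::str_length(syms))]
  paste0("(?:", paste(regex_escape(syms), collapse = "|"), ")")
}

#' Compile parse expressions for a property model
#'
#' Generates the surface patterns used by the sentence parser from the model
#' definition: a specifier alternation, a quantity grammar for the model's
#' dimension (all allowed units), and the combined
#' specifier--link-words--quantity pattern.
#'
#' @param model A `tadf_property_model`.
#' @return List with `specifier_re`, `quantity_re`, `link_re` (stringr
#'   regexes).
#' @export
compile_parse_expressions <- function(model) {
  if (length(model$specifiers) == 0) stop("empty specifier list for ", model$property_id)
  specs <- model$specifiers[order(-stringr::str_length(model$specifiers))]
  specifier_re <- paste0(
    "(?:", paste(regex_escape(specs), collapse = "|"), ")"
  )
  quantity_re <- paste0(
    "(", .number_re, ")(?:", .range_sep_re, "(", .number_re, "))?\\s*(",
    unit_alternation(model), ")?"
  )
  link_re <- paste0(
    "(?:\\s*(?:is|was|were|of|at|in|measured to be|found to be|estimated to be|",
    "determined to be|to be|as high as|as low as|reaches|reached|amounts to|",
    "about|approximately|around|up to|=|:|~)\\b?\\s*)+"
  )
  list(specifier_re = specifier_re, quantity_re = quantity_re, link_re = link_re)
}

#' Parse the first quantity in a text fragment
#'
#' Extracts the first number or range plus unit compatible with the model's
#' dimension. Supports decimals, ranges written with en dash, hyphen or
#' `"to"`, and `x10^n` / e-notation. A bare number without a unit yields
#' `NULL` for dimensioned properties; the fractional quantum-yield table
#' parser handles the unitless case.
#'
#' @param text Sentence or cell fragment.
#' @param model A `tadf_property_model`.
#' @param require_unit If `FALSE`, a unitless number is returned with
#'   `unit = ""`.
#' @param anchored Require the match at the start of `text`.
#' @return A `tadf_quantity` (`values`, `unit`, `raw_text`) or `NULL`.
#' @export
parse_quantity <- function(text, model, require_unit = TRUE, anchored = FALSE) {
  text <- canonical_unicode(text)
  ex <- model$compiled %||% compile_parse_expressions(model)
  pat <- if (anchored) paste0("^", ex$quantity_re) else ex$quantity_re
  m <- stringr::str_match(text, pat)
  if (is.na(m[1, 1])) return(NULL)
  unit <- m[1, 4]
  if (is.na(unit) || !nzchar(unit)) {
    if (require_unit) {
      # scan further along the string for a later number that does carry a unit
      if (!anchored) {
        rest_at <- stringr::str_locate(text, stringr::fixed(m[1, 1]))[1, 2]
        rest <- stringr::str_sub(text, rest_at + 1L)
        if (nzchar(rest)) return(parse_quantity(rest, model, require_unit = TRUE))
      }
      return(NULL)
    }
    unit <- ""
  }
  vals <- parse_number_token(m[1, 2])
  if (!is.na(m[1, 3]) && nzchar(m[1, 3])) {
    vals <- sort(c(vals, parse_number_token(m[1, 3])))
  }
  structure(
    list(values = vals, unit = unit, raw_text = stringr::str_trim(m[1, 1])),
    class = "tadf_quantity"
  )
}

parse_number_token <- function(tok) {
  tok <- stringr::str_replace_all(tok, "\\s", "")
  m <- stringr::str_match(tok, "^([-+]?[0-9]+(?:\\.[0-9]+)?)(?:x10\\^?([-+]?[0-9]+))?$")
  if (!is.na(m[1, 3])) {
    return(as.numeric(m[1, 2]) * 10 ^ as.numeric(m[1, 3]))
  }
  as.numeric(tok)
}

#' Convert a quantity to the model's standard unit
#'
#' Multiplies each value by the allowed unit's conversion factor; the energy
#' dimension accepts kJ/mol with the molar-gas conversion 96.485 kJ/mol per
#' eV. A unitless quantity (`unit = ""`) is treated as already being on the
#' standard scale only for the dimensionless-fraction property.
#'
#' @param q A `tadf_quantity`.
#' @param model A `tadf_property_model`.
#' @return Numeric vector of standard values.
#' @export
to_standard <- function(q, model) {
  if (!nzchar(q$unit)) {
    if (model$dimension == "dimensionless-fraction") return(q$values)
    stop("quantity has no unit for dimensioned property ", model$property_id)
  }
  unit <- canonical_unicode(q$unit)
  if (!unit %in% names(model$allowed_units)) {
    stop("unknown unit '", unit, "' for property ", model$property_id)
  }
  q$values * model$allowed_units[[unit]]
}

#' Convert standard values back to a given unit (inverse of [to_standard()])
#' @param values Numeric vector in the standard unit.
#' @param unit Target unit symbol.
#' @param model A `tadf_property_model`.
#' @return Numeric vector in `unit`.
#' @export
from_standard <- function(values, unit, model) {
  unit <- canonical_unicode(unit)
  if (!unit %in% names(model$allowed_units)) {
    stop("unknown unit '", unit, "' for property ", model$property_id)
  }
  values / model$allowed_units[[unit]]
}
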