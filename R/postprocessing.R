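# Cleaning of candidate records: physical-range filters, temperature
# standardization, and the experimental-vs-theoretical classification of
# singlet-triplet splittings.

# physically reasonable ranges on the standard scale; PLQY bounds inclusive
.physical_ranges <- list(
  lambda_em  = list(min = 300,  max = 1600, inclusive = FALSE),  # nm
  plqy       = list(min = 0,    max = 100,  inclusive = TRUE),   # %
  delta_e_st = list(min = -1.5, max = 1.5,  inclusive = FALSE),  # eV
  tau_d      = list(min = 0.1,  max = 1e7,  inclusive = FALSE)   # μs (100 ns .. 10 s)
)

#' Physical-range filter
#'
#' Drops a record iff any of its standard values lies outside the physically
#' reasonable range of its property: 300 nm < λ_EM < 1600 nm,
#' 0 % ≤ PLQY ≤ 100 %, -1.5 eV < ΔE_ST < 1.5 eV, 100 ns < τ_D < 10 s.
#' The quantum-yield bounds are inclusive; the others are exclusive.
#'
#' @param record A `tadf_candidate` with standard values.
#' @return List `(keep = TRUE)` or `(keep = FALSE, reason = string)`.
#' @export
filter_physical_range <- function(record) {
  rng <- .physical_ranges[[record$property_id]]
  if (is.null(rng)) return(list(keep = TRUE))
  v <- record$standard_value
  ok <- if (rng$inclusive) all(v >= rng$min & v <= rng$max)
    else all(v > rng$min & v < rng$max)
  if (ok) list(keep = TRUE)
  else list(keep = FALSE,
            reason = paste0(record$property_id, " value outside (",
                            rng$min, ", ", rng$max, ")"))
}

#' Standardize the temperature of a delayed-lifetime record
#'
#' Room-temperature flags are replaced by an explicit temperature of 293 K;
#' when both a flag and an extracted temperature are present, the explicit
#' value wins. Records with a non-physical temperature (≤ 0 K) are dropped.
#'
#' @param record A `tadf_candidate` for property `tau_d`.
#' @return The record with `extra$temperature` standardized (kelvin), or
#'   `NULL` when dropped.
#' @export
standardize_temperature <- function(record) {
  if (record$property_id != "tau_d") return(record)
  temp <- record$extra$temperature
  if (is.null(temp) && isTRUE(record$extra$room_temperature)) temp <- 293
  record$extra$room_temperature <- NULL
  if (!is.null(temp)) {
    if (temp <= 0) return(NULL)
    record$extra$temperature <- temp
  }
  record
}

#' Build the classification context of a record
#'
#' The context for the experimental-vs-theoretical classifier is the heading
#' of the section, the first sentence of the paragraph, and the sentence
#' containing the record, joined by single spaces (duplicates collapse when
#' the record sentence is itself the first sentence). Standalone table
#' records have no context and return `NULL`.
#'
#' @param record A `tadf_candidate`.
#' @param doc The `tadf_document` (unused by the default implementation;
#'   context parts are carried in the record's extra fields).
#' @return Context string or `NULL`.
#' @export
build_classifier_context <- function(record, doc = NULL) {
  if (!identical(record$provenance$parser, "sentence")) return(NULL)
  parts <- c(record$extra$section %||% "",
             record$extra$first_sentence %||% "",
             record$extra$sentence_text %||% "")
  parts <- parts[nzchar(parts)]
  parts <- parts[!duplicated(parts)]
  if (!length(parts)) return(NULL)
  paste(parts, collapse = " ")
}

.classifier_registry <- new.env(parent = emptyenv())

#' Register an is_experimental classifier
#' @param name Classifier id.
#' @param fn Function `function(context) -> TRUE/FALSE/NA`.
#' @export
register_classifier <- function(name, fn) {
  assign(name, fn, envir = .classifier_registry)
  invisible(name)
}

.theoretical_cues <- c("TD-DFT", "DFT", "calculat", "computed", "computation",
                       "simulat", "ab initio")
.experimental_cues <- c("measur", "onset", "phosphorescence spectr",
                        "fluorescence spectr", "experiment", "spectroscop")

#' Classify whether a ΔE_ST record is experimental
#'
#' Default keyword classifier: theoretical cues (DFT, TD-DFT, calculated,
#' computed, simulated) yield `FALSE`; experimental cues (measured, onset,
#' fluorescence/phosphorescence spectra) yield `TRUE`; no cue or both kinds
#' yield `NA` (unknown). Alternative trained classifiers can be plugged in
#' via [register_classifier()].
#'
#' @param context Context string from [build_classifier_context()], or `NULL`.
#' @param classifier Registered classifier id or a function.
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
classify_is_experimental <- function(context, classifier = "keyword") {
  if (is.null(context)) return(NA)
  if (is.character(classifier)) {
    fn <- if (exists(classifier, envir = .classifier_registry)) {
      get(classifier, envir = .classifier_registry)
    } else if (classifier == "keyword") {
      keyword_classifier
    } else stop("unknown classifier id: ", classifier)
  } else fn <- classifier
  fn(context)
}

keyword_classifier <- function(context) {
  lc <- tolower(context)
  theo <- any(stringr::str_detect(lc, stringr::fixed(tolower(.theoretical_cues))))
  expe <- any(stringr::str_detect(lc, stringr::fixed(tolower(.experimental_cues))))
  if (theo && !expe) return(FALSE)
  if (expe && !theo) return(TRUE)
  NA
}

.phase_keywords <- c("doped film", "neat film", "thin film", "film", "solid",
                     "toluene solution", "solution", "neat", "crystal",
                     "powder", "host")
.atmosphere_keywords <- list(
  nitrogen = c("N2", "nitrogen", "degassed", "argon", "inert"),
  air = c("air", "aerated", "ambient atmosphere")
)

#' Extract the phase mentioned in a record's source text
#' @param text The record's sentence or serialized cell text.
#' @return Phase keyword or `NULL`.
#' @export
extract_phase <- function(text) {
  lc <- tolower(text)
  for (k in .phase_keywords) {
    if (stringr::str_detect(lc, stringr::fixed(tolower(k)))) return(k)
  }
  NULL
}

#' Extract the measurement atmosphere mentioned in a record's source text
#' @param text The record's sentence or serialized cell text.
#' @return `"nitrogen"`, `"air"` or `"unknown"`.
#' @export
extract_atmosphere <- function(text) {
  for (atm in names(.atmosphere_keywords)) {
    for (k in .atmosphere_keywords[[atm]]) {
      re <- paste0("(?i)(?<![A-Za-z])", regex_escape(k), "(?![A-Za-z])")
      if (stringr::str_detect(text, re)) return(atm)
    }
  }
  "unknown"
}

#' Post-process a list of candidate records
#'
#' Applies, in order: temperature standardization (delayed lifetimes),
#' physical-range filtering, phase/atmosphere extraction (quantum yield and
#' emission wavelength), and is_experimental classification (singlet-triplet
#' splittings with a text context). Returns the surviving records plus a
#' per-reason drop report.
#'
#' @param records List of `tadf_candidate`.
#' @param doc Optional `tadf_document`.
#' @param classifier Classifier id or function for [classify_is_experimental()].
#' @return List with `records` and `drops` (named integer vector of reasons).
#' @export
postprocess_records <- function(records, doc = NULL, classifier = "keyword") {
  kept <- list()
  drops <- integer(0)
  bump <- function(reason) {
    cur <- if (reason %in% names(drops)) drops[[reason]] else 0L
    drops[reason] <<- cur + 1L
  }
  for (r in records) {
    r <- standardize_temperature(r)
    if (is.null(r)) { bump("non-physical temperature"); next }
    f <- filter_physical_range(r)
    if (!f$keep) { bump(f$reason); next }
    src <- r$extra$sentence_text %||% r$quantity$raw_text %||% ""
    if (r$property_id %in% c("plqy", "lambda_em")) {
      ph <- extract_phase(src)
      if (!is.null(ph)) r$extra$phase <- ph
    }
    if (r$property_id == "plqy") {
      r$extra$atmosphere <- extract_atmosphere(src)
    }
    if (r$property_id == "delta_e_st") {
      r$extra$is_experimental <- classify_is_experimental(
        build_classifier_context(r, doc), classifier
      )
    }
    kept[[length(kept) + 1L]] <- r
  }
  list(records = kept, drops = drops)
}
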