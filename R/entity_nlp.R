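# Sentence segmentation, pluggable chemical-entity tagging, and bracket/
# equality abbreviation detection.

# Periods after these tokens never end a sentence.
.non_terminal_abbrev <- c(
  "approx", "ca", "cf", "Fig", "Figs", "Eq", "Eqs", "Ref", "Refs", "et al",
  "e.g", "i.e", "vs", "Dr", "Prof", "no", "No", "wt", "Tab", "Sec", "resp"
)

#' Segment a paragraph into sentences
#'
#' Splits on sentence-final punctuation (`.`, `!`, `?`) followed by whitespace
#' and an upper-case letter or digit, while abbreviating periods inside
#' scientific prose ("approx.", "Fig.", "et al.") and decimal points never
#' split. Offsets are tracked so that the concatenation of sentence texts and
#' inter-sentence separators reconstructs the paragraph exactly.
#'
#' @param paragraph A single character string.
#' @return List of `tadf_sentence` objects, each with `text`, `start`, `end`
#'   (0-based half-open offsets into the paragraph), `tokens` and empty
#'   `cem_spans`.
#' @export
segment_sentences <- function(paragraph) {
  stopifnot(length(paragraph) == 1)
  if (!nzchar(paragraph)) return(list())

  chars <- stringr::str_length(paragraph)
  # candidate break points: terminator + whitespace + capital/digit/greek
  cand <- stringr::str_locate_all(
    paragraph, "[.!?](?=\\s+[\\p{Lu}\\p{Greek}0-9])"
  )[[1]]
  breaks <- integer(0)
  for (pos in cand[, 1]) {
    before <- stringr::str_sub(paragraph, 1, pos - 1)
    last_tok <- stringr::str_extract(before, "[A-Za-z.]+$")
    if (!is.na(last_tok) && last_tok %in% .non_terminal_abbrev) next
    breaks <- c(breaks, pos)
  }

  starts <- c(1L, integer(0))
  sentences <- list()
  start <- 1L
  for (b in c(breaks, chars)) {
    end <- min(b, chars)
    if (b == chars) end <- chars
    txt <- stringr::str_sub(paragraph, start, end)
    core <- stringr::str_trim(txt)
    if (nzchar(core)) {
      # offsets of the trimmed sentence inside the paragraph (0-based half-open)
      lead <- stringr::str_length(txt) - stringr::str_length(stringr::str_trim(txt, side = "left"))
      s0 <- start - 1L + lead
      sentences[[length(sentences) + 1L]] <- new_sentence(core, s0)
    }
    start <- end + 1L
    if (start > chars) break
  }
  sentences
}

new_sentence <- function(text, start = 0L) {
  structure(
    list(text = text, start = start, end = start + stringr::str_length(text),
         tokens = tokenize(text), cem_spans = list()),
    class = "tadf_sentence"
  )
}

# Coarse token classes: word, number, punct, symbol. Offsets 0-based half-open.
tokenize <- function(text) {
  pat <- "[\\p{L}\\p{Greek}][\\p{L}\\p{Greek}0-9'\\-]*|[-+]?[0-9]+(?:\\.[0-9]+)?|[[:punct:]]|\\S"
  loc <- stringr::str_locate_all(text, pat)[[1]]
  if (nrow(loc) == 0) return(list())
  lapply(seq_len(nrow(loc)), function(i) {
    surf <- stringr::str_sub(text, loc[i, 1], loc[i, 2])
    cls <- if (stringr::str_detect(surf, "^[-+]?[0-9]")) "number"
      else if (stringr::str_detect(surf, "^[\\p{L}\\p{Greek}]")) "word"
      else if (stringr::str_detect(surf, "^[[:punct:]]$")) "punct"
      else "symbol"
    list(surface = surf, start = loc[i, 1] - 1L, end = loc[i, 2], class = cls)
  })
}

regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# ---- tagger plugin registry --------------------------------------------------

.tagger_registry <- new.env(parent = emptyenv())

#' Register a chemical-entity tagger
#'
#' Taggers are deterministic functions `function(text) -> data.frame(start,
#' end, name)` with 0-based half-open offsets. The built-in `"lexicon"`
#' tagger is registered at load time.
#'
#' @param name Tagger id.
#' @param fn Tagger function.
#' @export
register_tagger <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .tagger_registry)
  invisible(name)
}

#' Construct the default lexicon + morphology tagger
#'
#' Matches lexicon names longest-first (case-insensitive for names, exact for
#' short labels), then applies morphology heuristics: tokens mixing digits,
#' upper- and lower-case letters (the "4CzIPN" shape) and systematic-name
#' fragments containing locants and brackets are tagged as chemical entity
#' mentions.
#'
#' @param lexicon Character vector of known compound names/labels.
#' @return A tagger function suitable for [register_tagger()].
#' @export
lexicon_tagger <- function(lexicon = character(0)) {
  lexicon <- unique(lexicon[nzchar(lexicon)])
  lexicon <- lexicon[order(-stringr::str_length(lexicon))]
  force(lexicon)
  function(text) {
    spans <- list()
    taken <- rep(FALSE, stringr::str_length(text))
    claim <- function(s, e) {
      if (any(taken[s:e])) return(FALSE)
      taken[s:e] <<- TRUE
      TRUE
    }
    for (name in lexicon) {
      is_label <- stringr::str_length(name) <= 4
      pat <- paste0("(?<![\\p{L}0-9])", regex_escape(name), "(?![\\p{L}0-9])")
      re <- if (is_label) stringr::regex(pat) else stringr::regex(pat, ignore_case = TRUE)
      loc <- stringr::str_locate_all(text, re)[[1]]
      for (i in seq_len(nrow(loc))) {
        if (claim(loc[i, 1], loc[i, 2])) {
          spans[[length(spans) + 1L]] <- list(
            start = loc[i, 1] - 1L, end = loc[i, 2],
            name = stringr::str_sub(text, loc[i, 1], loc[i, 2])
          )
        }
      }
    }
    # systematic-name fragments: locant prefixes with bracketed substituents
    sysname <- "(?<![\\p{L}0-9])[0-9]+(?:,[0-9]+)*-[A-Za-z][A-Za-z0-9]*\\((?:[^()]|\\([^()]*\\))*\\)[A-Za-z0-9,\\-]*(?![\\p{L}0-9])"
    loc <- stringr::str_locate_all(text, sysname)[[1]]
    for (i in seq_len(nrow(loc))) {
      if (claim(loc[i, 1], loc[i, 2])) {
        spans[[length(spans) + 1L]] <- list(
          start = loc[i, 1] - 1L, end = loc[i, 2],
          name = stringr::str_sub(text, loc[i, 1], loc[i, 2])
        )
      }
    }
    # morphology: mixed-case alphanumeric tokens like 4CzIPN, 2CzPN, DMAC-TRZ
    morph <- "(?<![\\p{L}0-9])(?:[0-9]+[A-Za-z][A-Za-z0-9\\-]*[A-Za-z][A-Za-z0-9]*|[A-Z][a-z]*[A-Z][A-Za-z0-9]*(?:-[A-Z][A-Za-z0-9]+)*)(?![\\p{L}0-9])"
    loc <- stringr::str_locate_all(text, morph)[[1]]
    for (i in seq_len(nrow(loc))) {
      surf <- stringr::str_sub(text, loc[i, 1], loc[i, 2])
      has_digit <- stringr::str_detect(surf, "[0-9]")
      has_lower <- stringr::str_detect(surf, "[a-z]")
      has_upper <- stringr::str_detect(surf, "[A-Z]")
      mixed <- (has_digit && has_lower && has_upper) ||
        (has_upper && has_lower && stringr::str_detect(surf, "-")) ||
        stringr::str_detect(surf, "[a-z][A-Z]")
      if (!mixed) next
      if (surf %in% .morphology_stoplist) next
      if (claim(loc[i, 1], loc[i, 2])) {
        spans[[length(spans) + 1L]] <- list(
          start = loc[i, 1] - 1L, end = loc[i, 2], name = surf
        )
      }
    }
    spans <- spans[order(vapply(spans, function(s) s$start, integer(1)))]
    spans
  }
}

# Specifier-like and unit-like tokens the morphology rule must not tag.
.morphology_stoplist <- c(
  "PLQY", "TADF", "RISC", "ISC", "OLED", "OLEDs", "DFT", "TD-DFT", "HOMO",
  "LUMO", "kJ", "eV", "meV", "nm", "kHz", "MHz", "GHz", "mol", "wt",
  "pH", "UV-Vis", "RT", "TfO"
)

#' Tag chemical entity mentions in a sentence
#'
#' @param sentence A `tadf_sentence`.
#' @param tagger A tagger function (from [lexicon_tagger()]) or a registered
#'   tagger id.
#' @return The sentence with `cem_spans` populated (sorted, non-overlapping).
#' @export
tag_cems <- function(sentence, tagger) {
  if (is.character(tagger)) {
    if (!exists(tagger, envir = .tagger_registry)) {
      stop("unknown tagger id: ", tagger)
    }
    tagger <- get(tagger, envir = .tagger_registry)
  }
  sentence$cem_spans <- tagger(sentence$text)
  sentence
}

# ---- abbreviation detection --------------------------------------------------

.bracket_pairs <- c("(" = ")", "[" = "]", "{" = "}")

#' Detect abbreviation definitions in a tagged sentence
#'
#' An abbreviation is detected when a chemical entity mention is immediately
#' preceded or followed (whitespace only in between) by a shorter entity in
#' matched brackets, or linked by an equality marker (`=` or `:`). The classic
#' letters-in-order (Schwartz--Hearst style) rule is retained for acronym
#' definitions whose long form is not a tagged chemical entity.
#'
#' @param sentence A `tadf_sentence` with `cem_spans` populated.
#' @return List of abbreviation pairs, each `list(short_form, long_form,
#'   evidence)` with evidence one of `"brackets"`, `"equality"`,
#'   `"letters-in-order"`.
#' @export
detect_abbreviations <- function(sentence) {
  text <- sentence$text
  pairs <- list()
  add_pair <- function(short, long, evidence) {
    short <- normalize_name(short); long <- normalize_name(long)
    if (!nzchar(short) || !nzchar(long)) return()
    if (stringr::str_length(short) >= stringr::str_length(long)) return()
    key <- paste(short, long)
    existing <- vapply(pairs, function(p) paste(p$short_form, p$long_form), character(1))
    if (key %in% existing) return()
    pairs[[length(pairs) + 1L]] <<- list(
      short_form = short, long_form = long, evidence = evidence
    )
  }

  for (span in sentence$cem_spans) {
    cem_text <- span$name
    after <- stringr::str_sub(text, span$end + 1L)
    # following bracketed entity:  CEM (SHORT)
    m <- stringr::str_match(after, "^\\s*([\\(\\[\\{])([^\\(\\)\\[\\]\\{\\}]+)([\\)\\]\\}])")
    if (!is.na(m[1, 1]) && .bracket_pairs[[m[1, 2]]] == m[1, 4]) {
      inner <- stringr::str_trim(m[1, 3])
      if (looks_like_entity(inner)) {
        pick_shorter(inner, cem_text, add_pair, "brackets")
      }
    }
    # preceding bracketed position:  SHORT (CEM)  i.e. the CEM is bracketed
    before <- stringr::str_sub(text, 1L, span$start)
    mb <- stringr::str_match(before, "([^\\s\\(\\)\\[\\]\\{\\}=:]+)\\s*([\\(\\[\\{])\\s*$")
    if (!is.na(mb[1, 1])) {
      close_needed <- .bracket_pairs[[mb[1, 3]]]
      m2 <- stringr::str_match(after, paste0("^\\s*\\", close_needed))
      # the candidate partner must not be a fragment of a longer tagged CEM
      cap_start0 <- stringr::str_length(before) - stringr::str_length(mb[1, 1])
      fragment_of_cem <- any(vapply(sentence$cem_spans, function(s) {
        s$start < cap_start0 && s$end > cap_start0
      }, logical(1)))
      if (!is.na(m2[1, 1]) && !fragment_of_cem && looks_like_entity(mb[1, 2])) {
        pick_shorter(mb[1, 2], cem_text, add_pair, "brackets")
      }
    }
    # equality markers:  SHORT = CEM   or   CEM = SHORT
    me <- stringr::str_match(after, "^\\s*[=:]\\s*([^,;.]+)")
    if (!is.na(me[1, 1]) && looks_like_entity(stringr::str_trim(me[1, 2]))) {
      pick_shorter(stringr::str_trim(me[1, 2]), cem_text, add_pair, "equality")
    }
    mp <- stringr::str_match(before, "([^\\s=:,;]+)\\s*[=:]\\s*$")
    if (!is.na(mp[1, 1]) && looks_like_entity(mp[1, 2])) {
      pick_shorter(mp[1, 2], cem_text, add_pair, "equality")
    }
  }

  # letters-in-order rule for non-CEM long forms:  long phrase (ABBR)
  cem_starts <- vapply(sentence$cem_spans, function(s) s$start, integer(1))
  lio <- stringr::str_locate_all(text, "\\(([A-Za-z0-9]{2,10})\\)")[[1]]
  caps <- stringr::str_match_all(text, "\\(([A-Za-z0-9]{2,10})\\)")[[1]]
  for (i in seq_len(nrow(lio))) {
    abbr <- caps[i, 2]
    open_at <- lio[i, 1]
    before <- stringr::str_sub(text, 1L, open_at - 1L)
    words <- stringr::str_split(stringr::str_trim(before), "\\s+")[[1]]
    n_take <- min(length(words), stringr::str_length(abbr) + 2L)
    if (n_take == 0) next
    cand_words <- tail(words, n_take)
    # shrink window until initials match in order
    for (k in rev(seq_len(n_take))) {
      phrase <- paste(tail(cand_words, k), collapse = " ")
      if (letters_in_order(abbr, phrase) &&
          stringr::str_length(abbr) < stringr::str_length(phrase)) {
        # skip when the long form is itself a tagged CEM span ending here
        is_cem_long <- any(vapply(sentence$cem_spans, function(s) {
          s$end >= open_at - 2L && s$start < open_at - 1L &&
            normalize_name(stringr::str_sub(text, s$start + 1L, s$end)) == normalize_name(phrase)
        }, logical(1)))
        if (!is_cem_long) add_pair(abbr, phrase, "letters-in-order")
        break
      }
    }
  }
  pairs
}

pick_shorter <- function(a, b, add_pair, evidence) {
  la <- stringr::str_length(normalize_name(a))
  lb <- stringr::str_length(normalize_name(b))
  if (la < lb) add_pair(a, b, evidence)
  else if (lb < la) add_pair(b, a, evidence)
  # equal lengths: no pair
}

# A short entity candidate: no internal whitespace runs of prose, limited
# length, contains letters/digits; rejects plain common words.
looks_like_entity <- function(x) {
  x <- stringr::str_trim(x)
  if (!nzchar(x)) return(FALSE)
  if (stringr::str_detect(x, "\\s")) return(FALSE)
  if (stringr::str_length(x) > 40) return(FALSE)
  if (stringr::str_detect(x, "^[0-9.]+$")) return(FALSE)  # bare numbers
  if (tolower(x) %in% .common_word_stoplist) return(FALSE)
  stringr::str_detect(x, "[A-Za-z]")
}

.common_word_stoplist <- c(
  "blue", "red", "green", "yellow", "white", "the", "a", "an", "film", "films",
  "solid", "solution", "neat", "doped", "left", "right", "top", "bottom"
)

# Do the letters of `abbr` occur in order in `phrase` (case-insensitive),
# with the first letter starting a word?
letters_in_order <- function(abbr, phrase) {
  a <- stringr::str_to_lower(stringr::str_remove_all(abbr, "[^A-Za-z]"))
  p <- stringr::str_to_lower(phrase)
  if (!nzchar(a)) return(FALSE)
  first_initials <- stringr::str_to_lower(
    stringr::str_sub(stringr::str_split(p, "\\s+")[[1]], 1, 1)
  )
  if (!stringr::str_sub(a, 1, 1) %in% first_initials) return(FALSE)
  pos <- 0L
  pc <- stringr::str_split(p, "")[[1]]
  for (ch in stringr::str_split(a, "")[[1]]) {
    idx <- which(pc == ch)
    idx <- idx[idx > pos]
    if (length(idx) == 0) return(FALSE)
    pos <- idx[1]
  }
  TRUE
}
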