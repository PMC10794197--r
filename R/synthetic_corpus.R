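# Synthetic-corpus generator: fixture articles in the supported markup
# dialects with gold-standard property annotations, so every pipeline stage
# is testable without any download.

xml_escape <- function(x) {
  x <- stringr::str_replace_all(x, stringr::fixed("&"), "&amp;")
  x <- stringr::str_replace_all(x, stringr::fixed("<"), "&lt;")
  stringr::str_replace_all(x, stringr::fixed(">"), "&gt;")
}

#' Specification of a synthetic corpus
#'
#' Defaults emulate a small TADF-article corpus: 24 documents, one sentence
#' fact per property per document plus a three-row summary table combining a
#' plain wavelength column, a fractional quantum-yield column, a combined
#' singlet/triplet/splitting column and a shared prompt/delayed lifetime
#' column; ubiquitous solvent/atmosphere distractors planted in every
#' document so blocklist construction is exercised; half of the compounds
#' introduced through a systematic-name/abbreviation definition.
#'
#' @param n_documents Number of articles.
#' @param facts_per_property Sentence facts per property per document.
#' @param table_rows Rows of the per-document summary table.
#' @param distractors Common solvent/reagent names planted as distractor
#'   mentions (never gold compounds).
#' @param distractor_prob Probability that each distractor appears in a
#'   document.
#' @param abbrev_prob Probability that a compound is introduced via a long
#'   systematic name with a bracketed abbreviation.
#' @param dialects Markup dialects cycled over documents.
#' @param noise List of robustness switches (all off by default):
#'   `missing_units` plants sentence facts without units (not extractable,
#'   lowers recall).
#' @param seed Integer seed; identical spec and seed yield byte-identical
#'   corpora.
#' @return A `tadf_corpus_spec` list.
#' @export
corpus_spec <- function(n_documents = 24, facts_per_property = 1,
                        table_rows = 3,
                        distractors = c("toluene", "nitrogen", "chloroform",
                                        "dichloromethane"),
                        distractor_prob = 1,
                        abbrev_prob = 0.5,
                        dialects = c("xml-like", "html-like"),
                        noise = list(missing_units = FALSE),
                        seed = 42) {
  structure(
    list(n_documents = n_documents, facts_per_property = facts_per_property,
         table_rows = table_rows, distractors = distractors,
         distractor_prob = distractor_prob, abbrev_prob = abbrev_prob,
         dialects = dialects, noise = noise, seed = seed),
    class = "tadf_corpus_spec"
  )
}

.name_frag1 <- c("Cz", "Ac", "Px", "Tz", "Bz", "Qx")
.name_frag2 <- c("PN", "IPN", "TRZ", "BN", "CN", "DPS")
.sys_cores <- c("carbazol", "acridin", "phenoxazin")
.sys_tails <- c("dicyanobenzene", "dicyanopyridine", "benzonitrile")

# deterministic unique short names across the corpus (digit + mixed case)
make_short_names <- function(n) {
  grid <- expand.grid(d = 2:9, f1 = .name_frag1, f2 = .name_frag2,
                      stringsAsFactors = FALSE)
  stopifnot(n <= nrow(grid))
  idx <- sample.int(nrow(grid), n)
  paste0(grid$d[idx], grid$f1[idx], grid$f2[idx])
}

# schematic SMILES per systematic-name tail (locants not structurally
# encoded; the corpus lookup table is synthetic by construction)
.tail_smiles <- c(
  dicyanobenzene = "N#Cc1cc(-n2c3ccccc3c3ccccc32)c(-n2c3ccccc3c3ccccc32)cc1C#N",
  dicyanopyridine = "N#Cc1cc(-n2c3ccccc3c3ccccc32)c(-n2c3ccccc3c3ccccc32)nc1C#N",
  benzonitrile = "N#Cc1ccc(-n2c3ccccc3c3ccccc32)c(-n2c3ccccc3c3ccccc32)c1"
)

# deterministic unique systematic names (one per short name, used only when
# the compound is introduced through an abbreviation definition)
make_long_names <- function(n) {
  grid <- expand.grid(
    l1 = c("1,2", "2,3", "3,4", "1,3", "2,4", "1,4"),
    l2 = c("4,5", "5,6", "4,6", "5,7", "6,7", "4,7"),
    core = .sys_cores, tail = .sys_tails,
    stringsAsFactors = FALSE
  )
  stopifnot(n <= nrow(grid))
  idx <- sample.int(nrow(grid), n)
  data.frame(
    name = paste0(grid$l1[idx], "-Bis(", grid$core[idx], "-9-yl)-",
                  grid$l2[idx], "-", grid$tail[idx]),
    smiles = unname(.tail_smiles[grid$tail[idx]]),
    stringsAsFactors = FALSE
  )
}

rnd_lambda <- function() sample(350:750, 1)
rnd_plqy <- function() sample(5:99, 1)
rnd_frac_plqy <- function() round(stats::runif(1, 0.05, 0.99), 2)
rnd_est <- function() round(stats::runif(1, 0.02, 0.45), 2)
rnd_taud <- function() round(stats::runif(1, 0.5, 9.9), 1)
rnd_es <- function() round(stats::runif(1, 2.5, 3.3), 2)

gold_record <- function(doc_id, property_id, values, unit, standard,
                        names, labels = character(0), temperature = NULL) {
  extra <- list()
  if (!is.null(temperature)) extra$temperature <- temperature
  structure(list(
    property_id = property_id,
    quantity = structure(list(values = values, unit = unit, raw_text = NULL),
                         class = "tadf_quantity"),
    standard_value = standard,
    compound = list(names = names, labels = labels),
    extra = extra,
    metadata = list(),
    provenance = list(doc_id = doc_id, parser = "gold")
  ), class = "tadf_candidate")
}

#' Generate one synthetic article with its gold records
#'
#' @param spec A `tadf_corpus_spec`.
#' @param doc_index 1-based document index (controls dialect and DOI).
#' @param compounds Character vector of pre-assigned unique short names for
#'   this document (length `4 * facts_per_property + table_rows`).
#' @param long_names Parallel character vector of unique systematic names
#'   (used when a compound is introduced through an abbreviation).
#' @return List with `markup` (file content string), `dialect`, `doc_id`,
#'   `gold` (list of gold records), `distractors_used`.
#' @export
generate_document <- function(spec, doc_index, compounds,
                              long_names = rep(NA_character_,
                                               length(compounds))) {
  dialect <- spec$dialects[((doc_index - 1) %% length(spec$dialects)) + 1]
  doc_id <- sprintf("10.5555/synth.%03d", doc_index)
  gold <- list()
  paras <- list()   # list of (section, text)
  k <- spec$facts_per_property

  comp_iter <- local({
    i <- 0L
    function() { i <<- i + 1L; compounds[[i]] }
  })

  distractors_used <- spec$distractors[
    stats::runif(length(spec$distractors)) <= spec$distractor_prob
  ]
  intro <- paste0(
    "Purely organic emitters with small singlet-triplet gaps were studied. ",
    if (length(distractors_used)) {
      paste0("All solvents such as ",
             paste(distractors_used, collapse = " and "),
             " were used as received. ")
    } else "",
    "Photophysical measurements were carried out on quartz substrates."
  )
  paras[[length(paras) + 1L]] <- list(section = "Introduction", text = intro)

  # compounds used in property sentences, optionally defined via abbreviation
  sentence_compounds <- character(0)
  synth_sentences <- character(0)
  abbrev_of <- list()
  for (i in seq_len(4 * k)) {
    short <- comp_iter()
    sentence_compounds <- c(sentence_compounds, short)
    long <- long_names[[match(short, compounds)]]
    if (stats::runif(1) <= spec$abbrev_prob && !is.na(long)) {
      abbrev_of[[short]] <- long
      synth_sentences <- c(synth_sentences, paste0(
        long, " (", short, ") was synthesized in ",
        if (length(distractors_used)) distractors_used[1] else "solution", "."
      ))
    } else {
      synth_sentences <- c(synth_sentences, paste0(
        short, " was prepared following the literature procedure."
      ))
    }
  }
  paras[[length(paras) + 1L]] <- list(
    section = "Synthesis", text = paste(synth_sentences, collapse = " ")
  )

  gold_names <- function(short) {
    if (!is.null(abbrev_of[[short]])) c(short, abbrev_of[[short]]) else short
  }

  ci <- 0L
  next_comp <- function() { ci <<- ci + 1L; sentence_compounds[[ci]] }

  # emission wavelength sentences
  for (i in seq_len(k)) {
    cpd <- next_comp()
    v <- rnd_lambda()
    if (i %% 2 == 1) {
      txt <- paste0("The emission maximum of ", cpd, " is at ", v, " nm.")
    } else {
      txt <- paste0(cpd, " shows an emission maximum of ", v,
                    " nm in a doped film.")
    }
    paras[[length(paras) + 1L]] <- list(section = "Photophysical properties",
                                        text = txt)
    gold[[length(gold) + 1L]] <- gold_record(
      doc_id, "lambda_em", v, "nm", v, gold_names(cpd)
    )
  }
  # quantum yield sentences
  for (i in seq_len(k)) {
    cpd <- next_comp()
    v <- rnd_plqy()
    if (i %% 2 == 1) {
      txt <- paste0("The PLQY of ", cpd, " is ", v,
                    "% in a doped film under nitrogen.")
    } else {
      txt <- paste0(cpd, " exhibits a PLQY of ", v, "% in toluene solution.")
    }
    paras[[length(paras) + 1L]] <- list(section = "Photophysical properties",
                                        text = txt)
    gold[[length(gold) + 1L]] <- gold_record(
      doc_id, "plqy", v, "%", v, gold_names(cpd)
    )
  }
  # singlet-triplet splitting sentences; alternate direct and theme-resolved
  for (i in seq_len(k)) {
    cpd <- next_comp()
    v <- rnd_est()
    if (i %% 2 == 1) {
      txt <- paste0("The ΔEST of ", cpd, " was measured to be ", v, " eV.")
    } else {
      txt <- paste0(cpd, " films were cast from solution. The ΔEST was ",
                    v, " eV.")
    }
    paras[[length(paras) + 1L]] <- list(section = "Photophysical properties",
                                        text = txt)
    gold[[length(gold) + 1L]] <- gold_record(
      doc_id, "delta_e_st", v, "eV", v, gold_names(cpd)
    )
  }
  # delayed lifetime sentences: explicit temperature or room temperature
  for (i in seq_len(k)) {
    cpd <- next_comp()
    v <- rnd_taud()
    if (i %% 2 == 1) {
      txt <- paste0("The delayed lifetime of ", cpd, " is ", v,
                    " μs at 300 K.")
      temp <- 300
    } else {
      txt <- paste0("The delayed lifetime of ", cpd,
                    " was measured to be ", v, " μs at room temperature.")
      temp <- 293
    }
    paras[[length(paras) + 1L]] <- list(section = "Photophysical properties",
                                        text = txt)
    gold[[length(gold) + 1L]] <- gold_record(
      doc_id, "tau_d", v, "μs", v, gold_names(cpd), temperature = temp
    )
  }

  # summary table: compound column + the three special-parser columns
  table_compounds <- vapply(seq_len(spec$table_rows), function(i) comp_iter(),
                            character(1))
  rows <- lapply(table_compounds, function(cpd) {
    lam <- rnd_lambda()
    frac <- rnd_frac_plqy()
    est <- rnd_est(); es <- rnd_es(); et <- round(es - est, 2)
    taud <- rnd_taud(); taup <- sample(5:99, 1)
    gold[[length(gold) + 1L]] <<- gold_record(doc_id, "lambda_em", lam, "nm",
                                              lam, cpd)
    gold[[length(gold) + 1L]] <<- gold_record(doc_id, "plqy", frac, "", frac * 100,
                                              cpd)
    gold[[length(gold) + 1L]] <<- gold_record(doc_id, "delta_e_st", est, "eV",
                                              est, cpd)
    gold[[length(gold) + 1L]] <<- gold_record(doc_id, "tau_d", taud, "μs",
                                              taud, cpd)
    list(
      cpd = cpd,
      cells = c(cpd, as.character(lam), format(frac, nsmall = 2),
                paste0(format(es, nsmall = 2), "/", format(et, nsmall = 2),
                       "/", format(est, nsmall = 2)),
                paste0(taup, "/", format(taud, nsmall = 1)), "2019")
    )
  })
  headers <- c("Compounds", "λem (nm)", "ΦPL", "ES/ET/ΔEST (eV)",
               "τp/τd (ns/μs)", "Year")

  markup <- render_markup(
    dialect = dialect,
    metadata = list(
      doi = doc_id,
      title = sprintf("Photophysics of donor-acceptor emitters %d", doc_index),
      authors = "A. Author; B. Author",
      journal = "Journal of Synthetic Photophysics",
      year = "2019"
    ),
    paras = paras,
    table = list(caption = "Summary of photophysical data.",
                 headers = headers, rows = lapply(rows, `[[`, "cells"))
  )
  list(markup = markup, dialect = dialect, doc_id = doc_id, gold = gold,
       distractors_used = distractors_used)
}

render_markup <- function(dialect, metadata, paras, table) {
  esc <- xml_escape
  table_lines <- c(
    "  <table>",
    paste0("    <caption>", esc(table$caption), "</caption>"),
    paste0("    <tr>", paste0("<th>", esc(table$headers), "</th>",
                              collapse = ""), "</tr>"),
    vapply(table$rows, function(r) {
      paste0("    <tr>", paste0("<td>", esc(r), "</td>", collapse = ""), "</tr>")
    }, character(1)),
    "  </table>"
  )
  sections <- split(
    vapply(paras, `[[`, character(1), "text"),
    factor(vapply(paras, `[[`, character(1), "section"),
           levels = unique(vapply(paras, `[[`, character(1), "section")))
  )
  body_lines <- unlist(lapply(names(sections), function(sec) {
    h <- if (dialect == "xml-like") {
      paste0("  <h>", esc(sec), "</h>")
    } else {
      paste0("  <h2>", esc(sec), "</h2>")
    }
    c(h, paste0("  <p>", esc(sections[[sec]]), "</p>"))
  }))

  if (dialect == "xml-like") {
    meta_lines <- c("  <meta>",
                    vapply(names(metadata), function(k) {
                      paste0("    <", k, ">", esc(metadata[[k]]), "</", k, ">")
                    }, character(1)),
                    "  </meta>")
    paste(c("<article>", meta_lines, body_lines, table_lines, "</article>", ""),
          collapse = "\n")
  } else {
    meta_lines <- c("  <head>",
                    paste0("    <title>", esc(metadata$title), "</title>"),
                    vapply(setdiff(names(metadata), "title"), function(k) {
                      paste0('    <meta name="', k, '" content="',
                             esc(metadata[[k]]), '"/>')
                    }, character(1)),
                    "  </head>")
    paste(c("<html>", meta_lines, "  <body>",
            paste0("  ", body_lines), paste0("  ", table_lines),
            "  </body>", "</html>", ""),
          collapse = "\n")
  }
}

#' Generate a synthetic corpus on disk
#'
#' Writes `docs/doc-XXX.xml|.html`, `gold.json` (gold records),
#' `planted_frequencies.json` (per-name document counts of planted
#' distractors and compounds, the oracle for frequency-table construction),
#' `lexicon.txt` (distractor names for the lexicon tagger) and
#' `name_smiles.tsv` (corpus-local lookup table for the SMILES backend).
#'
#' @param spec A `tadf_corpus_spec`.
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with `gold`, `planted_frequencies`, `files`.
#' @export
generate_corpus <- function(spec, out_dir) {
  dir.create(file.path(out_dir, "docs"), recursive = TRUE, showWarnings = FALSE)
  n_per_doc <- 4 * spec$facts_per_property + spec$table_rows
  withr::with_seed(as.integer(spec$seed), {
    all_names <- if (spec$n_documents > 0) {
      make_short_names(spec$n_documents * n_per_doc)
    } else character(0)
    all_long <- if (spec$n_documents > 0) {
      make_long_names(spec$n_documents * n_per_doc)
    } else data.frame(name = character(0), smiles = character(0))
    gold <- list()
    planted <- list()
    files <- character(0)
    for (d in seq_len(spec$n_documents)) {
      sel <- ((d - 1) * n_per_doc + 1):(d * n_per_doc)
      comp <- all_names[sel]
      g <- generate_document(spec, d, comp, all_long$name[sel])
      ext <- if (g$dialect == "xml-like") ".xml" else ".html"
      path <- file.path(out_dir, "docs", sprintf("doc-%03d%s", d, ext))
      writeLines(g$markup, path, useBytes = TRUE)
      files <- c(files, path)
      gold <- c(gold, g$gold)
      for (nm in c(g$distractors_used, comp)) {
        planted[[nm]] <- (planted[[nm]] %||% 0L) + 1L
      }
    }
    write_records(gold, file.path(out_dir, "gold.json"), "json")
    jsonlite::write_json(planted, file.path(out_dir, "planted_frequencies.json"),
                         auto_unbox = TRUE)
    writeLines(spec$distractors, file.path(out_dir, "lexicon.txt"),
               useBytes = TRUE)
    writeLines(
      c("name\tsmiles", paste(all_long$name, all_long$smiles, sep = "\t")),
      file.path(out_dir, "name_smiles.tsv"), useBytes = TRUE
    )
    invisible(list(gold = gold, planted_frequencies = planted, files = files))
  })
}
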