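# Shared fixture builders: all fixtures are constructed in code at test time.

write_fixture <- function(markup, ext = ".xml") {
  path <- tempfile(fileext = ext)
  writeLines(markup, path, useBytes = TRUE)
  path
}

fixture_doc <- function(markup, dialect = "xml-like",
                        ext = if (dialect == "xml-like") ".xml" else ".html") {
  read_document(write_fixture(markup, ext), dialect)
}

# minimal article with one heading, two paragraphs and one table
basic_article <- function() {
  paste(
    "<article>",
    "  <meta>",
    "    <doi>10.5555/test.001</doi>",
    "    <title>A test article</title>",
    "    <authors>A. Author</authors>",
    "    <journal>J. Tests</journal>",
    "    <year>2020</year>",
    "  </meta>",
    "  <h>Photophysical properties</h>",
    "  <p>The PLQY of 2CzPN is 68% in toluene.</p>",
    "  <p>The delayed lifetime of 2CzPN is 3.2 μs at 300 K.</p>",
    "  <table>",
    "    <caption>Data</caption>",
    "    <tr><th>Compounds</th><th>λem (nm)</th></tr>",
    "    <tr><td>2CzPN</td><td>470</td></tr>",
    "  </table>",
    "</article>",
    sep = "\n"
  )
}

# a tadf_table built through the public reader
fixture_table <- function(header_rows, body_rows, caption = "T") {
  th <- vapply(header_rows, function(r) {
    paste0("    <tr>", paste0("<th", ifelse(nzchar(names2(r)), paste0(' colspan="', names2(r), '"'), ""),
                              ">", r, "</th>", collapse = ""), "</tr>")
  }, character(1))
  td <- vapply(body_rows, function(r) {
    paste0("    <tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>")
  }, character(1))
  markup <- paste(c("<article>", "  <table>",
                    paste0("    <caption>", caption, "</caption>"),
                    th, td, "  </table>", "</article>"), collapse = "\n")
  doc <- fixture_doc(markup)
  Filter(function(e) e$kind == "table", doc$elements)[[1]]$table
}

names2 <- function(x) {
  n <- names(x)
  if (is.null(n)) rep("", length(x)) else n
}

# serialized cell string built directly (headers outer->inner, then cell)
cell_string <- function(headers, cell) {
  paste(c(headers, cell), collapse = CELL_SEPARATOR)
}

# small corpus shared across pipeline/acceptance tests, generated once
corpus_cache <- new.env(parent = emptyenv())

shared_corpus <- function() {
  if (is.null(corpus_cache$dir)) {
    dir <- tempfile("synthcorpus")
    generate_corpus(corpus_spec(), dir)
    corpus_cache$dir <- dir
  }
  corpus_cache$dir
}

shared_pipeline_result <- function() {
  if (is.null(corpus_cache$result)) {
    dir <- shared_corpus()
    cfg <- pipeline_config(
      lexicon = file.path(dir, "lexicon.txt"),
      threshold_fraction = 0.25,
      smiles_backend = lookup_smiles_backend(file.path(dir, "name_smiles.tsv"))
    )
    corpus_cache$result <- run_pipeline(dir, cfg)
    corpus_cache$gold <- read_records(file.path(dir, "gold.json"), "json")
  }
  list(result = corpus_cache$result, gold = corpus_cache$gold,
       dir = shared_corpus())
}

random_clean_record <- function(doc_id = "10.5555/r.1") {
  props <- c("lambda_em", "plqy", "delta_e_st", "tau_d")
  p <- sample(props, 1)
  v <- switch(p, lambda_em = runif(1, 100, 2000), plqy = runif(1, -20, 130),
              delta_e_st = runif(1, -2, 2), tau_d = runif(1, 0.01, 2e7))
  unit <- switch(p, lambda_em = "nm", plqy = "%", delta_e_st = "eV",
                 tau_d = "μs")
  structure(list(
    property_id = p,
    quantity = structure(list(values = v, unit = unit, raw_text = NULL),
                         class = "tadf_quantity"),
    standard_value = v,
    compound = list(names = paste0(sample(2:9, 1), "CzX", sample(LETTERS, 1)),
                    labels = character(0)),
    extra = list(),
    metadata = list(doi = doc_id),
    provenance = list(doc_id = doc_id, parser = "sentence")
  ), class = "tadf_candidate")
}
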