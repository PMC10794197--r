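#' @importFrom stats setNames
#' @importFrom utils head tail
NULL

#' Normalize a chemical name
#'
#' Standardizes a chemical entity mention by removing unnecessary whitespace:
#' leading/trailing whitespace is stripped, internal whitespace runs are
#' collapsed to a single space, and spaces adjacent to hyphens, commas and
#' brackets are removed. Internal single spaces between alphabetic words are
#' kept so that multi-word names ("boron nitride") survive. The operation is
#' idempotent.
#'
#' @param raw Character vector of raw names.
#' @return Character vector of normalized names.
#' @examples
#' normalize_name("  4,5- Bis(carbazol-9-yl) ")
#' @export
normalize_name <- function(raw) {
  x <- stringr::str_replace_all(raw, "\\s+", " ")
  x <- stringr::str_trim(x)
  # remove spaces adjacent to hyphens, commas and brackets
  x <- stringr::str_replace_all(x, " ?([\\-,\\(\\)\\[\\]\\{\\}]) ?", "\\1")
  x
}

#' Map unicode homoglyphs to canonical forms
#'
#' Publisher markup uses several look-alike code points for the Greek letters
#' and signs that appear in photophysical property specifiers. This maps the
#' micro sign to Greek mu, the increment sign to capital delta, the minus sign
#' to ASCII hyphen-minus, and multiplication sign variants to "x".
#'
#' @param x Character vector.
#' @return Character vector with homoglyphs mapped.
#' @export
canonical_unicode <- function(x) {
  map <- c(
    "µ" = "μ",  # micro sign -> greek mu
    "∆" = "Δ",  # increment -> greek Delta
    "−" = "-",       # minus sign -> hyphen-minus
    "×" = "x"        # multiplication sign
  )
  stringr::str_replace_all(x, map)
}

dialect_tags <- list(
  `xml-like` = list(
    root = "article", meta = "meta", heading = "h", paragraph = "p",
    table = "table", row = "tr", header_cell = "th", data_cell = "td",
    caption = "caption"
  ),
  `html-like` = list(
    root = "html", meta = "head", heading = c("h1", "h2", "h3"),
    paragraph = "p", table = "table", row = "tr", header_cell = "th",
    data_cell = "td", caption = "caption"
  )
)

new_element <- function(kind, text = "", table = NULL, section = "", metadata = FALSE) {
  structure(
    list(kind = kind, text = text, table = table, section = section,
         metadata = metadata),
    class = "tadf_element"
  )
}

#' Read a marked-up article into a Document
#'
#' Parses a UTF-8 markup file of one of the two supported fixture dialects
#' into an ordered `tadf_document`: headings, paragraphs and tables in source
#' order, with the metadata/citation block mapped to the document metadata and
#' flagged so that no property records can originate from it.
#'
#' The `xml-like` dialect uses `<article>` as root, a `<meta>` block of
#' citation fields (`<doi>`, `<title>`, `<authors>`, `<journal>`, `<year>`),
#' `<h>` headings, `<p>` paragraphs and `<table>` elements built from
#' `<caption>`, `<tr>`, `<th>` and `<td>` (with optional `colspan`). The
#' `html-like` dialect uses `<html>`/`<head>`/`<body>`, `<meta name= content=>`
#' citation tags, `<h1>`-`<h3>` headings, and the same table tags.
#'
#' @param path Path to the markup file.
#' @param dialect `"xml-like"` or `"html-like"`.
#' @return A `tadf_document` with fields `doc_id`, `metadata`, `elements`,
#'   `source_dialect`.
#' @export
read_document <- function(path, dialect = c("xml-like", "html-like")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(
    xml2::read_xml(path, encoding = "UTF-8"),
    error = function(e) stop("malformed markup in ", path, ": ", conditionMessage(e))
  )
  tags <- dialect_tags[[dialect]]

  metadata <- list()
  elements <- list()
  current_section <- ""

  if (dialect == "xml-like") {
    meta_node <- xml2::xml_find_first(doc, "./meta")
    if (!inherits(meta_node, "xml_missing")) {
      kids <- xml2::xml_children(meta_node)
      metadata <- setNames(
        as.list(xml2::xml_text(kids)),
        xml2::xml_name(kids)
      )
      elements[[length(elements) + 1L]] <- new_element(
        "metadata", text = xml2::xml_text(meta_node), metadata = TRUE
      )
    }
    body_nodes <- xml2::xml_find_all(doc, "./h | ./p | ./table")
  } else {
    head_node <- xml2::xml_find_first(doc, "./head")
    if (!inherits(head_node, "xml_missing")) {
      metas <- xml2::xml_find_all(head_node, "./meta")
      metadata <- setNames(
        as.list(xml2::xml_attr(metas, "content")),
        xml2::xml_attr(metas, "name")
      )
      title <- xml2::xml_find_first(head_node, "./title")
      if (!inherits(title, "xml_missing")) metadata$title <- xml2::xml_text(title)
      elements[[length(elements) + 1L]] <- new_element(
        "metadata", text = xml2::xml_text(head_node), metadata = TRUE
      )
    }
    body_nodes <- xml2::xml_find_all(
      doc, "./body/h1 | ./body/h2 | ./body/h3 | ./body/p | ./body/table"
    )
  }

  for (node in body_nodes) {
    nm <- xml2::xml_name(node)
    if (nm %in% tags$heading) {
      current_section <- stringr::str_trim(xml2::xml_text(node))
      elements[[length(elements) + 1L]] <- new_element(
        "heading", text = current_section, section = current_section
      )
    } else if (nm == tags$paragraph) {
      elements[[length(elements) + 1L]] <- new_element(
        "paragraph", text = stringr::str_trim(xml2::xml_text(node)),
        section = current_section
      )
    } else if (nm == tags$table) {
      elements[[length(elements) + 1L]] <- new_element(
        "table", table = parse_table_node(node), section = current_section
      )
    }
  }

  doc_id <- metadata$doi %||% tools::file_path_sans_ext(basename(path))
  structure(
    list(doc_id = doc_id, metadata = metadata, elements = elements,
         source_dialect = dialect),
    class = "tadf_document"
  )
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

# Flatten a <table> node: header rows (all-<th> rows, outermost first) are
# expanded by colspan and resolved into per-column ordered header lists.
parse_table_node <- function(node) {
  caption_node <- xml2::xml_find_first(node, "./caption")
  caption <- if (inherits(caption_node, "xml_missing")) "" else
    stringr::str_trim(xml2::xml_text(caption_node))

  rows <- xml2::xml_find_all(node, "./tr")
  header_rows <- list()
  body <- list()
  for (r in rows) {
    cells <- xml2::xml_find_all(r, "./th | ./td")
    is_header <- all(xml2::xml_name(cells) == "th") && length(cells) > 0
    texts <- stringr::str_trim(xml2::xml_text(cells))
    spans <- suppressWarnings(as.integer(xml2::xml_attr(cells, "colspan")))
    spans[is.na(spans)] <- 1L
    expanded <- rep(texts, times = spans)
    if (is_header && length(body) == 0) {
      header_rows[[length(header_rows) + 1L]] <- expanded
    } else {
      body[[length(body) + 1L]] <- expanded
    }
  }

  ncol <- if (length(body)) max(lengths(body)) else
    if (length(header_rows)) max(lengths(header_rows)) else 0L
  body <- lapply(body, function(r) { length(r) <- ncol; r[is.na(r)] <- ""; r })
  header_rows <- lapply(header_rows, function(r) {
    length(r) <- ncol; r[is.na(r)] <- ""; r
  })

  column_headers <- lapply(seq_len(ncol), function(j) {
    hs <- vapply(header_rows, function(r) r[[j]], character(1))
    hs[nzchar(hs)]
  })

  structure(
    list(caption = caption, header_rows = header_rows, body = body,
         column_headers = column_headers, ncol = ncol),
    class = "tadf_table"
  )
}

#' Iterate over parseable document elements
#'
#' Returns the ordered elements of a document, excluding (by default) elements
#' flagged as metadata/citation, which are never parsed for property records.
#'
#' @param doc A `tadf_document`.
#' @param include_metadata Include metadata-flagged elements (default `FALSE`).
#' @return List of `tadf_element`.
#' @export
doc_elements <- function(doc, include_metadata = FALSE) {
  els <- doc$elements
  if (!include_metadata) {
    els <- Filter(function(e) !isTRUE(e$metadata), els)
  }
  els
}

#' @export
print.tadf_document <- function(x, ...) {
  kinds <- vapply(x$elements, function(e) e$kind, character(1))
  cat("<tadf_document> ", x$doc_id, " (", x$source_dialect, ")\n", sep = "")
  cat("  elements:", paste(sprintf("%s=%d", names(table(kinds)), table(kinds)),
                           collapse = ", "), "\n")
  invisible(x)
}
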