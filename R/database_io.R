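# Serialization of clean records to the published schema (CSV with dotted
# column names for nested fields, JSON with preserved nesting) and reading
# them back.

.base_columns <- c("doc_id", "model_name", "compound.names", "compound.labels",
                   "compound.smiles", "value", "units", "standard_value",
                   "record_method", "metadata", "phase", "atmosphere",
                   "temperature", "is_experimental")

json_cell <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = FALSE, digits = NA, null = "null"))
}

#' Flatten records into the schema data frame
#'
#' Nested fields become dotted column names; list fields (compound names and
#' labels, value, standard_value, metadata) are JSON-encoded in-cell. All
#' columns are character so that write/read round trips are byte-exact.
#'
#' @param records List of records (from the pipeline or [read_records()]).
#' @return A data frame with the schema columns.
#' @export
records_to_frame <- function(records) {
  rows <- lapply(records, function(r) {
    data.frame(
      doc_id = r$provenance$doc_id %||% "",
      model_name = r$property_id,
      compound.names = json_cell(as.character(r$compound$names %||% character(0))),
      compound.labels = json_cell(as.character(r$compound$labels %||% character(0))),
      compound.smiles = r$compound$smiles %||% "",
      value = json_cell(r$quantity$values),
      units = r$quantity$unit %||% "",
      standard_value = json_cell(r$standard_value),
      record_method = r$provenance$parser %||% "",
      metadata = json_cell(r$metadata %||% setNames(list(), character(0))),
      phase = r$extra$phase %||% "",
      atmosphere = r$extra$atmosphere %||% "",
      temperature = if (is.null(r$extra$temperature)) "" else
        as.character(r$extra$temperature),
      is_experimental = if (is.null(r$extra$is_experimental)) "" else
        if (is.na(r$extra$is_experimental)) "unknown" else
          as.character(r$extra$is_experimental),
      stringsAsFactors = FALSE, check.names = FALSE
    )
  })
  if (!length(rows)) {
    return(as.data.frame(
      setNames(rep(list(character(0)), length(.base_columns)), .base_columns),
      check.names = FALSE
    ))
  }
  do.call(rbind, rows)
}

frame_to_records <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    extra <- list()
    if (nzchar(row$phase)) extra$phase <- row$phase
    if (nzchar(row$atmosphere)) extra$atmosphere <- row$atmosphere
    if (nzchar(row$temperature)) extra$temperature <- as.numeric(row$temperature)
    if (nzchar(row$is_experimental)) {
      extra$is_experimental <- if (row$is_experimental == "unknown") NA else
        as.logical(row$is_experimental)
    }
    compound <- list(
      names = as.character(jsonlite::fromJSON(row$compound.names)),
      labels = as.character(jsonlite::fromJSON(row$compound.labels))
    )
    if (nzchar(row$compound.smiles)) compound$smiles <- row$compound.smiles
    meta <- jsonlite::fromJSON(row$metadata, simplifyVector = TRUE)
    structure(list(
      property_id = row$model_name,
      quantity = structure(
        list(values = as.numeric(jsonlite::fromJSON(row$value)),
             unit = row$units, raw_text = NULL),
        class = "tadf_quantity"
      ),
      standard_value = as.numeric(jsonlite::fromJSON(row$standard_value)),
      compound = compound,
      extra = extra,
      metadata = if (length(meta)) as.list(meta) else list(),
      provenance = list(doc_id = row$doc_id, parser = row$record_method)
    ), class = "tadf_candidate")
  })
}

#' Write records to CSV or JSON
#'
#' CSV flattens nested fields to dotted column names with list fields
#' JSON-encoded in-cell (RFC 4180, UTF-8, header row); JSON preserves the
#' nested structure as an array of record objects. Records written and read
#' back compare equal, and a write-read-write cycle is byte-identical.
#'
#' @param records List of records.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @export
write_records <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- records_to_frame(records)
  if (format == "csv") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.csv(df, con, row.names = FALSE, fileEncoding = "UTF-8",
                     quote = TRUE, eol = "\n")
  } else {
    objs <- lapply(seq_len(nrow(df)), function(i) {
      row <- df[i, , drop = FALSE]
      obj <- list(
        doc_id = row$doc_id,
        model_name = row$model_name,
        compound = list(
          names = as.character(jsonlite::fromJSON(row$compound.names)),
          labels = as.character(jsonlite::fromJSON(row$compound.labels))
        ),
        value = as.numeric(jsonlite::fromJSON(row$value)),
        units = row$units,
        standard_value = as.numeric(jsonlite::fromJSON(row$standard_value)),
        record_method = row$record_method,
        metadata = jsonlite::fromJSON(row$metadata, simplifyVector = FALSE)
      )
      if (nzchar(row$compound.smiles)) obj$compound$smiles <- row$compound.smiles
      if (nzchar(row$phase)) obj$phase <- row$phase
      if (nzchar(row$atmosphere)) obj$atmosphere <- row$atmosphere
      if (nzchar(row$temperature)) obj$temperature <- as.numeric(row$temperature)
      if (nzchar(row$is_experimental)) obj$is_experimental <- row$is_experimental
      obj
    })
    jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(path)
}

#' Read records written by [write_records()]
#'
#' @param path Input file path.
#' @param format `"csv"` or `"json"`.
#' @return List of records.
#' @export
read_records <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8")
    missing <- setdiff(setdiff(.base_columns, "compound.smiles"), names(df))
    if (length(missing)) {
      stop("missing mandatory columns: ", paste(missing, collapse = ", "))
    }
    if (!"compound.smiles" %in% names(df)) df$compound.smiles <- ""
    return(frame_to_records(df))
  }
  objs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(objs, function(o) {
    extra <- list()
    if (!is.null(o$phase)) extra$phase <- o$phase
    if (!is.null(o$atmosphere)) extra$atmosphere <- o$atmosphere
    if (!is.null(o$temperature)) extra$temperature <- as.numeric(o$temperature)
    if (!is.null(o$is_experimental)) {
      extra$is_experimental <- if (identical(o$is_experimental, "unknown")) NA
        else as.logical(o$is_experimental)
    }
    compound <- list(names = as.character(unlist(o$compound$names)),
                     labels = as.character(unlist(o$compound$labels)))
    if (!is.null(o$compound$smiles)) compound$smiles <- o$compound$smiles
    meta <- lapply(o$metadata %||% list(), function(x) unname(unlist(x)))
    structure(list(
      property_id = o$model_name,
      quantity = structure(
        list(values = as.numeric(unlist(o$value)), unit = o$units %||% "",
             raw_text = NULL),
        class = "tadf_quantity"
      ),
      standard_value = as.numeric(unlist(o$standard_value)),
      compound = compound,
      extra = extra,
      metadata = meta,
      provenance = list(doc_id = o$doc_id %||% "", parser = o$record_method %||% "")
    ), class = "tadf_candidate")
  })
}
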