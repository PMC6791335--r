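# CSV and JSON I/O: the ingest path (CSV export -> records -> exchange
# JSON) and the exchange format itself.
#
# CSV is RFC 4180: quoted fields may contain the delimiter, doubled
# quotes and embedded newlines.  The reader is a small state machine
# rather than read.csv because the contract requires (a) honouring
# embedded newlines and (b) reporting ragged rows by their 1-based data
# row number; base readers surface neither.

# --- CSV --------------------------------------------------------------------

#' Read an RFC 4180 CSV stream into a row table
#'
#' @param source Path to a CSV file, or a character vector of its lines.
#' @param delimiter Single field-separator character (default comma).
#' @return A `bioscoop_row_table`: list with `header` (character vector of
#'   unique column names) and `rows` (list of character vectors, one per
#'   data row, each of length `length(header)`).
#' @export
read_csv_table <- function(source, delimiter = ",") {
  if (!is.character(delimiter) || length(delimiter) != 1L ||
      nchar(delimiter) != 1L) {
    stop("delimiter must be a single character", call. = FALSE)
  }
  if (length(source) == 1L && !grepl("[\n\r]", source) && file.exists(source)) {
    txt <- paste(readLines(source, warn = FALSE, encoding = "UTF-8"),
                 collapse = "\n")
  } else {
    txt <- paste(source, collapse = "\n")
  }
  # tolerate a UTF-8 byte-order mark
  txt <- sub("^\uFEFF", "", txt)
  if (!nzchar(trimws(txt))) stop("no header: CSV stream is empty", call. = FALSE)

  rows <- parse_csv_text(txt, delimiter)
  header <- trimws(rows[[1L]])
  if (anyDuplicated(header)) {
    stop(sprintf("duplicate column name(s): %s",
                 paste(unique(header[duplicated(header)]), collapse = ", ")),
         call. = FALSE)
  }
  data <- rows[-1L]
  n <- length(header)
  for (i in seq_along(data)) {
    if (length(data[[i]]) != n) {
      stop(sprintf("ragged row %d: expected %d cells, found %d",
                   i, n, length(data[[i]])), call. = FALSE)
    }
  }
  structure(list(header = header, rows = data),
            class = "bioscoop_row_table")
}

# state-machine CSV tokenizer; returns a list of character vectors
parse_csv_text <- function(txt, delimiter) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  rows <- list()
  fields <- character()
  buf <- character()
  in_quotes <- FALSE
  i <- 1L
  n <- length(chars)
  flush_field <- function() {
    fields[[length(fields) + 1L]] <<- paste(buf, collapse = "")
    buf <<- character()
  }
  flush_row <- function() {
    flush_field()
    rows[[length(rows) + 1L]] <<- fields
    fields <<- character()
  }
  while (i <= n) {
    ch <- chars[i]
    if (in_quotes) {
      if (ch == '"') {
        if (i < n && chars[i + 1L] == '"') {  # doubled quote -> literal quote
          buf[length(buf) + 1L] <- '"'
          i <- i + 1L
        } else {
          in_quotes <- FALSE
        }
      } else {
        buf[length(buf) + 1L] <- ch
      }
    } else if (ch == '"') {
      in_quotes <- TRUE
    } else if (ch == delimiter) {
      flush_field()
    } else if (ch == "\r") {
      if (i < n && chars[i + 1L] == "\n") i <- i + 1L
      flush_row()
    } else if (ch == "\n") {
      flush_row()
    } else {
      buf[length(buf) + 1L] <- ch
    }
    i <- i + 1L
  }
  if (in_quotes) stop("unterminated quoted field at end of input", call. = FALSE)
  if (length(buf) > 0L || length(fields) > 0L) flush_row()
  rows
}

# quote cells only when needed; doubled-quote escaping
csv_escape <- function(x, delimiter) {
  needs <- grepl(paste0("[\"\n\r", delimiter, "]"), x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs], fixed = TRUE), '"')
  x
}

write_csv_lines <- function(header, rows, path, delimiter = ",") {
  lines <- c(paste(csv_escape(header, delimiter), collapse = delimiter),
             vapply(rows, function(r) {
               paste(csv_escape(r, delimiter), collapse = delimiter)
             }, ""))
  writeLines(enc2utf8(lines), path, useBytes = TRUE)
  invisible(length(rows))
}

# --- column mapping ---------------------------------------------------------

#' Column mapping for CSV conversion
#'
#' @param entries Named character vector: CSV column name -> internal
#'   record field (dotted path); the composite targets `extras`
#'   ("name=value;...") and `medical_events` ("CODE|type|date;...") are
#'   supported alongside scalar fields.
#' @param date_format strptime format used to parse CSV date cells.
#' @param missing_tokens Cell values treated as absent.
#' @return A `bioscoop_mapping` object.
#' @export
column_mapping <- function(entries,
                           date_format = "%Y-%m-%d",
                           missing_tokens = c("", "NA", "null")) {
  entries <- vapply(entries, identity, "")
  known <- .FIELD_TABLE$internal
  bad <- setdiff(unname(entries), known)
  if (length(bad)) {
    stop(sprintf("mapping targets not in the schema: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(unname(entries))) {
    stop("two CSV columns map to the same record field", call. = FALSE)
  }
  structure(list(entries = entries, date_format = date_format,
                 missing_tokens = missing_tokens),
            class = "bioscoop_mapping")
}

#' Read a column mapping from a YAML or JSON config file
#'
#' The file carries `mapping:` (column -> field entries), `dateFormat:`
#' and `missingTokens:`.
#'
#' @param path Path to the config file (`.yaml`/`.yml` or `.json`).
#' @return A `bioscoop_mapping` object.
#' @export
read_column_mapping <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  column_mapping(unlist(cfg$mapping),
                 date_format = cfg$dateFormat %||% "%Y-%m-%d",
                 missing_tokens = as.character(cfg$missingTokens %||%
                                                c("", "NA", "null")))
}

#' Default column mapping shipped with the package
#'
#' Matches the CSV headers written by [write_cohort_csv()].
#' @return A `bioscoop_mapping` object.
#' @export
default_column_mapping <- function() {
  read_column_mapping(system.file("extdata", "default-mapping.yaml",
                                  package = "bioscoop", mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- row table -> records ---------------------------------------------------

#' Convert a row table to records
#'
#' One record per data row, in row order.  Cells equal to a missing
#' token yield absent fields; numeric and date cells are parsed
#' according to the target field's schema type.  Rows whose cells fail
#' to parse, and rows whose assembled record fails validation, are
#' excluded from the returned records but counted in the report, so
#' `length(records) + invalid rows == nrow(table)`.
#'
#' @param table A `bioscoop_row_table` from [read_csv_table()].
#' @param mapping A `bioscoop_mapping`; default [default_column_mapping()].
#' @return List with `records` (valid, canonicalized) and `report`
#'   (a `bioscoop_report` covering parse failures and schema violations,
#'   indexed by 1-based data-row number).
#' @export
rows_to_records <- function(table, mapping = default_column_mapping()) {
  stopifnot(inherits(table, "bioscoop_row_table"))
  stopifnot(inherits(mapping, "bioscoop_mapping"))
  cols <- names(mapping$entries)
  missing_cols <- setdiff(cols, table$header)
  if (length(missing_cols)) {
    stop(sprintf("mapped column(s) absent from CSV header: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  col_idx <- match(cols, table$header)
  types <- .FIELD_TABLE$type[match(unname(mapping$entries),
                                   .FIELD_TABLE$internal)]

  parse_violations <- list()
  records <- vector("list", length(table$rows))
  for (i in seq_along(table$rows)) {
    row <- table$rows[[i]]
    rec <- list()
    for (k in seq_along(cols)) {
      cell <- row[[col_idx[k]]]
      if (cell %in% mapping$missing_tokens) next
      target <- unname(mapping$entries[k])
      parsed <- parse_cell(cell, types[k], mapping$date_format)
      if (is.null(parsed$value)) {
        parse_violations[[length(parse_violations) + 1L]] <-
          violation(i, target, parsed$rule, parsed$message)
      } else {
        rec[[target]] <- parsed$value
      }
    }
    records[[i]] <- rec
  }

  schema_rep <- validate_records(records)
  sv <- schema_rep$violations
  if (length(parse_violations)) {
    # a cell that failed to parse already has its parse violation; do not
    # also report the resulting hole as a missing required field
    pv <- do.call(rbind, parse_violations)
    drop <- sv$rule_id == "required_nonempty" &
      paste(sv$record_index, sv$path) %in% paste(pv$record_index, pv$path)
    sv <- sv[!drop, , drop = FALSE]
  }
  all_viol <- c(parse_violations,
                if (nrow(sv)) split(sv, seq_len(nrow(sv))))
  report <- new_report(all_viol)
  bad <- unique(report$violations$record_index)
  keep <- setdiff(seq_along(records), bad)
  list(records = lapply(records[keep], canonicalize_record, check = FALSE),
       report = report)
}

# parse one CSV cell according to the target field type; returns
# list(value=) on success or list(value=NULL, rule=, message=) on failure
parse_cell <- function(cell, type, date_format) {
  switch(type,
    id = , string = , enum = list(value = cell),
    date = {
      d <- parse_date_format(cell, date_format)
      if (is.na(d)) {
        list(value = NULL, rule = "date_parse",
             message = sprintf("cannot parse '%s' as a date (%s)",
                               cell, date_format))
      } else list(value = d)
    },
    number = {
      x <- suppressWarnings(as.numeric(cell))
      if (is.na(x)) {
        list(value = NULL, rule = "number_parse",
             message = sprintf("cannot parse '%s' as a number", cell))
      } else list(value = x)
    },
    extras = parse_extras_cell(cell),
    events = parse_events_cell(cell)
  )
}

# "name=value;name=value"
parse_extras_cell <- function(cell) {
  parts <- strsplit(cell, ";", fixed = TRUE)[[1L]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1L]]
    x <- if (length(kv) == 2L) suppressWarnings(as.numeric(kv[2L])) else NA
    if (length(kv) != 2L || is.na(x)) {
      return(list(value = NULL, rule = "extras_parse",
                  message = sprintf("cannot parse extras cell '%s'", cell)))
    }
    out[[trimws(kv[1L])]] <- x
  }
  list(value = out)
}

# "CODE|type|date;CODE|type|date" — date may be empty
parse_events_cell <- function(cell) {
  parts <- strsplit(cell, ";", fixed = TRUE)[[1L]]
  out <- list()
  for (p in parts) {
    bits <- strsplit(p, "|", fixed = TRUE)[[1L]]
    if (length(bits) < 2L || length(bits) > 3L) {
      return(list(value = NULL, rule = "events_parse",
                  message = sprintf("cannot parse medical-events cell '%s'", cell)))
    }
    e <- list(icd10_code = trimws(bits[1L]), event_type = trimws(bits[2L]))
    if (length(bits) == 3L && nzchar(trimws(bits[3L]))) {
      e$event_date <- trimws(bits[3L])
    }
    out[[length(out) + 1L]] <- e
  }
  list(value = out)
}

# render one record field as a CSV cell (inverse of parse_cell)
format_cell <- function(value, type) {
  if (is.null(value)) return("")
  switch(type,
    number = as.character(value),
    extras = paste(vapply(seq_along(value), function(j) {
      paste0(names(value)[j], "=", as.character(value[[j]]))
    }, ""), collapse = ";"),
    events = paste(vapply(value, function(e) {
      paste(e$icd10_code, e$event_type, e$event_date %||% "", sep = "|")
    }, ""), collapse = ";"),
    as.character(value)
  )
}

# --- exchange JSON ----------------------------------------------------------

# internal (snake_case) record -> on-disk (lowerCamelCase) named list
record_to_json_list <- function(record) {
  out <- list()
  for (f in names(record)) {
    j <- .FIELD_TABLE$json[match(f, .FIELD_TABLE$internal)]
    if (is.na(j)) j <- f
    x <- record[[f]]
    if (identical(f, "medical_events")) {
      x <- lapply(x, function(e) {
        ej <- list(icd10Code = e$icd10_code, eventType = e$event_type)
        if (!is.null(e$event_date)) ej$eventDate <- e$event_date
        ej[order(names(ej))]
      })
    }
    out[[j]] <- x
  }
  out[order(names(out))]
}

# on-disk named list -> internal record; unknown keys kept verbatim so the
# validator can flag them
record_from_json_list <- function(obj) {
  out <- list()
  for (j in names(obj)) {
    f <- .FIELD_TABLE$internal[match(j, .FIELD_TABLE$json)]
    if (is.na(f)) f <- j
    x <- obj[[j]]
    if (identical(f, "medical_events") && is.list(x)) {
      x <- lapply(x, function(e) {
        if (!is.list(e)) return(e)
        ei <- list()
        for (k in names(e)) {
          ei[[switch(k, icd10Code = "icd10_code", eventType = "event_type",
                     eventDate = "event_date", k)]] <- e[[k]]
        }
        ei
      })
    }
    out[[f]] <- x
  }
  out
}

records_to_json <- function(records) {
  payload <- lapply(records, record_to_json_list)
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Write records as exchange JSON
#'
#' Emits a UTF-8 JSON array of canonicalized records with sorted keys;
#' two writes of the same input are byte-identical.  If any record is
#' invalid nothing is written: the function stops with a
#' `bioscoop_validation_error` carrying the validation report in its
#' `report` field.
#'
#' @param records List of valid records.
#' @param path Destination file path.
#' @return (Invisibly) the number of records written.
#' @export
write_bioscoop_json <- function(records, path) {
  records <- canonicalize_records(records, check = TRUE)
  writeLines(records_to_json(records), path, useBytes = TRUE)
  invisible(length(records))
}

#' Read exchange JSON
#'
#' Parses a UTF-8 JSON array of record objects, maps on-disk
#' lowerCamelCase names to internal fields and validates.  Valid
#' records are returned canonicalized; invalid ones are dropped and
#' reported.  Satisfies the round-trip law
#' `read(write(x))$records == canonicalize(x)` element-wise.
#'
#' @param source Path to a JSON file, or a JSON string.
#' @return List with `records` and `report` (a `bioscoop_report`).
#' @export
read_bioscoop_json <- function(source) {
  if (length(source) == 1L && !grepl("[{}\\[\n]", source) &&
      file.exists(source)) {
    txt <- paste(readLines(source, warn = FALSE, encoding = "UTF-8"),
                 collapse = "\n")
  } else {
    txt <- paste(source, collapse = "\n")
  }
  first <- sub("^\\s*", "", txt)
  if (!startsWith(first, "[")) {
    stop("structural error: top level must be a JSON array of records",
         call. = FALSE)
  }
  parsed <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                     error = function(e) {
                       stop(sprintf("structural error: invalid JSON (%s)",
                                    conditionMessage(e)), call. = FALSE)
                     })
  for (i in seq_along(parsed)) {
    if (!is.list(parsed[[i]]) ||
        (length(parsed[[i]]) > 0L && is.null(names(parsed[[i]])))) {
      stop(sprintf("structural error: element %d is not a record object", i),
           call. = FALSE)
    }
  }
  records <- lapply(parsed, record_from_json_list)
  report <- validate_records(records)
  keep <- setdiff(seq_along(records), unique(report$violations$record_index))
  list(records = lapply(records[keep], canonicalize_record, check = FALSE),
       report = report)
}
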