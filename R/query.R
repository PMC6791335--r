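# Solr-style query engine: parse field/phrase/range terms combined with
# AND/OR/NOT, evaluate them over an in-memory record set.
#
# Grammar (recursive descent, character positions reported on error):
#   query  := clause (WS ("AND"|"OR") WS clause)*     equal precedence,
#                                                     left associative
#   clause := ["NOT" WS] ( "(" query ")" | term )
#   term   := field ":" ( bare | "quoted phrase" | "[" lo " TO " hi "]" )
# "*" is an open range bound; operator keywords are upper-case; mixing
# AND and OR at one level without parentheses is rejected (real Solr's
# precedence rules are notoriously non-boolean; in a sample-search
# setting a silent wrong cohort is worse than an error).  Exclusive
# "{ }" ranges are reserved and rejected.  Matching is exact full
# string, case-insensitive — a deliberate simplification of Solr's
# tokenized text matching; numeric fields compare numerically, dates
# as ISO strings (lexicographic == chronological).

# query-field registry: canonical name -> type; aliases resolve at parse
.QUERY_FIELDS <- c(
  donorId = "string", collectionId = "string", sampleId = "string",
  timestamp = "date", dataSource = "string", birthDate = "date",
  birthPlace = "string", residencePlace = "string", sex = "string",
  ethnicOrigin = "string", skinTone = "string", hairColour = "string",
  eyeColour = "string", bloodGroup = "string", heightCm = "number",
  weightKg = "number", waistCm = "number", hipCm = "number",
  whr = "number", bmi = "number", ci = "number",
  icd10 = "string", eventType = "string", materialForm = "string"
)

# aliases: the questionnaire field is "sex" but search traditionally says
# "gender"; snake_case spellings are accepted as well
.QUERY_ALIASES <- c(
  gender = "sex",
  donor_id = "donorId", collection_id = "collectionId",
  sample_id = "sampleId", data_source = "dataSource",
  birth_date = "birthDate", birth_place = "birthPlace",
  residence_place = "residencePlace", ethnic_origin = "ethnicOrigin",
  skin_tone = "skinTone", hair_colour = "hairColour",
  eye_colour = "eyeColour", blood_group = "bloodGroup",
  height_cm = "heightCm", weight_kg = "weightKg", waist_cm = "waistCm",
  hip_cm = "hipCm", icd10_code = "icd10", event_type = "eventType",
  material_form = "materialForm"
)

resolve_field <- function(name) {
  if (name %in% names(.QUERY_ALIASES)) unname(.QUERY_ALIASES[name]) else name
}

# --- AST constructors -------------------------------------------------------

field_term <- function(field, value) {
  structure(list(kind = "field", field = field, value = value),
            class = "bioscoop_query")
}
phrase_term <- function(field, phrase) {
  structure(list(kind = "phrase", field = field, value = phrase),
            class = "bioscoop_query")
}
range_term <- function(field, lo, hi) {
  structure(list(kind = "range", field = field, lo = lo, hi = hi),
            class = "bioscoop_query")
}
bool_node <- function(op, children) {
  stopifnot(op %in% c("AND", "OR", "NOT"))
  if (op == "NOT" && length(children) != 1L) {
    stop("NOT takes exactly one child", call. = FALSE)
  }
  if (op != "NOT" && length(children) < 2L) {
    stop(sprintf("%s takes at least two children", op), call. = FALSE)
  }
  structure(list(kind = "bool", op = op, children = children),
            class = "bioscoop_query")
}

parse_error <- function(pos, msg) {
  stop(structure(class = c("bioscoop_parse_error", "error", "condition"),
                 list(message = sprintf("parse error at position %d: %s",
                                        pos, msg),
                      call = NULL, position = pos)))
}

# --- tokenizer --------------------------------------------------------------

# tokens: list(type = "LPAREN"|"RPAREN"|"AND"|"OR"|"NOT"|"TERM", pos, ...)
tokenize_query <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  i <- 1L
  tokens <- list()
  push <- function(tok) tokens[[length(tokens) + 1L]] <<- tok
  is_word_char <- function(ch) grepl("[A-Za-z0-9_.*+-]", ch)

  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t", "\n")) { i <- i + 1L; next }
    if (ch == "(") { push(list(type = "LPAREN", pos = i)); i <- i + 1L; next }
    if (ch == ")") { push(list(type = "RPAREN", pos = i)); i <- i + 1L; next }
    if (ch == "{" || ch == "}") {
      parse_error(i, "exclusive '{ }' range bounds are reserved; use [lo TO hi]")
    }
    if (!is_word_char(ch)) parse_error(i, sprintf("unexpected character '%s'", ch))

    start <- i
    while (i <= n && is_word_char(chars[i])) i <- i + 1L
    word <- paste(chars[start:(i - 1L)], collapse = "")

    if (word %in% c("AND", "OR", "NOT") && (i > n || chars[i] != ":")) {
      push(list(type = word, pos = start))
      next
    }
    if (i > n || chars[i] != ":") {
      parse_error(start, sprintf("expected ':' after field name '%s'", word))
    }
    i <- i + 1L  # consume ':'
    field <- resolve_field(word)
    if (i > n) parse_error(i, "missing value after ':'")

    if (chars[i] == '"') {                       # phrase
      i <- i + 1L
      vstart <- i
      while (i <= n && chars[i] != '"') i <- i + 1L
      if (i > n) parse_error(vstart - 1L, "unbalanced quote")
      phrase <- if (i > vstart) {
        paste(chars[vstart:(i - 1L)], collapse = "")
      } else ""
      i <- i + 1L
      push(list(type = "TERM", pos = start,
                node = phrase_term(field, phrase)))
    } else if (chars[i] == "[") {                # range
      bstart <- i
      while (i <= n && chars[i] != "]") i <- i + 1L
      if (i > n) parse_error(bstart, "unbalanced bracket in range")
      body <- paste(chars[(bstart + 1L):(i - 1L)], collapse = "")
      i <- i + 1L
      m <- regmatches(body, regexec("^\\s*(\\S+)\\s+TO\\s+(\\S+)\\s*$", body))[[1L]]
      if (length(m) != 3L) {
        parse_error(bstart, "range must have the form [lo TO hi]")
      }
      lo <- m[2L]; hi <- m[3L]
      lo_n <- suppressWarnings(as.numeric(lo))
      hi_n <- suppressWarnings(as.numeric(hi))
      if (!is.na(lo_n) && !is.na(hi_n) && lo_n > hi_n) {
        parse_error(bstart, sprintf("inverted range bounds: %s > %s", lo, hi))
      }
      push(list(type = "TERM", pos = start,
                node = range_term(field,
                                  if (lo == "*") NULL else lo,
                                  if (hi == "*") NULL else hi)))
    } else if (chars[i] == "{") {
      parse_error(i, "exclusive '{ }' range bounds are reserved; use [lo TO hi]")
    } else {                                     # bare value
      vstart <- i
      while (i <= n && !chars[i] %in% c(" ", "\t", "\n", "(", ")")) i <- i + 1L
      if (i == vstart) parse_error(vstart, "missing value after ':'")
      value <- paste(chars[vstart:(i - 1L)], collapse = "")
      push(list(type = "TERM", pos = start, node = field_term(field, value)))
    }
  }
  tokens
}

# --- parser -----------------------------------------------------------------

#' Parse a Solr-style query string
#'
#' Supports `field:value`, `field:"quoted phrase"`,
#' `numeric_field:[lo TO hi]` (inclusive, `*` for an open bound) and
#' the upper-case operators `AND`, `OR`, `NOT` with parentheses.
#' Mixing AND and OR at the same level requires parentheses.  `gender`
#' is an alias for `sex`; snake_case field spellings are accepted.
#'
#' @param text Non-empty query string.
#' @return The query AST (`bioscoop_query`).
#' @examples
#' parse_query("gender:male AND bmi:[18 TO 23]")
#' @export
parse_query <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    parse_error(1L, "empty query")
  }
  tokens <- tokenize_query(text)
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$i <- 1L
  node <- parse_query_level(state, text)
  if (state$i <= length(tokens)) {
    tok <- tokens[[state$i]]
    parse_error(tok$pos, if (tok$type == "RPAREN") {
      "unbalanced ')'"
    } else "unexpected trailing input")
  }
  node
}

peek <- function(state) {
  if (state$i <= length(state$tokens)) state$tokens[[state$i]] else NULL
}
advance <- function(state) {
  tok <- state$tokens[[state$i]]
  state$i <- state$i + 1L
  tok
}

parse_query_level <- function(state, text) {
  clauses <- list(parse_clause(state, text))
  ops <- character()
  repeat {
    tok <- peek(state)
    if (is.null(tok) || !tok$type %in% c("AND", "OR")) break
    op_tok <- advance(state)
    nxt <- peek(state)
    if (is.null(nxt) || nxt$type %in% c("AND", "OR", "RPAREN")) {
      parse_error(op_tok$pos, sprintf("dangling operator %s", op_tok$type))
    }
    ops <- c(ops, op_tok$type)
    clauses[[length(clauses) + 1L]] <- parse_clause(state, text)
  }
  if (length(ops) == 0L) return(clauses[[1L]])
  if (length(unique(ops)) > 1L) {
    parse_error(state$tokens[[state$i - 2L]]$pos,
                "mixing AND and OR requires parentheses")
  }
  bool_node(ops[1L], clauses)
}

parse_clause <- function(state, text) {
  tok <- peek(state)
  if (is.null(tok)) parse_error(nchar(text) + 1L, "expected a clause")
  if (tok$type == "NOT") {
    advance(state)
    child <- parse_clause(state, text)
    return(bool_node("NOT", list(child)))
  }
  if (tok$type == "LPAREN") {
    advance(state)
    node <- parse_query_level(state, text)
    closing <- peek(state)
    if (is.null(closing) || closing$type != "RPAREN") {
      parse_error(tok$pos, "unbalanced '('")
    }
    advance(state)
    return(node)
  }
  if (tok$type == "TERM") return(advance(state)$node)
  parse_error(tok$pos, sprintf("unexpected %s", tok$type))
}

#' @export
print.bioscoop_query <- function(x, ...) {
  cat(deparse_query(x), "\n")
  invisible(x)
}

deparse_query <- function(node) {
  switch(node$kind,
    field = paste0(node$field, ":", node$value),
    phrase = sprintf('%s:"%s"', node$field, node$value),
    range = sprintf("%s:[%s TO %s]", node$field,
                    node$lo %||% "*", node$hi %||% "*"),
    bool = if (node$op == "NOT") {
      paste0("NOT (", deparse_query(node$children[[1L]]), ")")
    } else {
      paste0("(", paste(vapply(node$children, deparse_query, ""),
                        collapse = paste0(" ", node$op, " ")), ")")
    }
  )
}

# --- record flattening ------------------------------------------------------

#' Flatten a record into a query field view
#'
#' Maps a nested record to the flat Solr-style field names used in
#' queries: donor fields under their camelCase names (`sex` also
#' exposed as `gender`), derived indices under `whr`/`bmi`/`ci`, dates
#' as ISO strings, and medical-event codes flattened to the
#' multi-valued fields `icd10` and `eventType`.  Absent fields are
#' absent from the view.
#'
#' @param record A valid record.
#' @return Named list: query field name -> scalar or vector of values.
#' @export
flatten_record <- function(record) {
  view <- list()
  for (f in names(record)) {
    j <- .FIELD_TABLE$json[match(f, .FIELD_TABLE$internal)]
    if (is.na(j) || f %in% c("extras", "medical_events")) next
    view[[j]] <- record[[f]]
  }
  ev <- record$medical_events
  if (length(ev)) {
    view$icd10 <- vapply(ev, function(e) e$icd10_code, "")
    view$eventType <- vapply(ev, function(e) e$event_type, "")
  }
  if (!is.null(view$sex)) view$gender <- view$sex
  view
}

# --- evaluation -------------------------------------------------------------

check_known_fields <- function(node) {
  if (node$kind == "bool") {
    for (ch in node$children) check_known_fields(ch)
  } else if (!node$field %in% names(.QUERY_FIELDS)) {
    stop(sprintf("query error: unknown field '%s'", node$field), call. = FALSE)
  }
  invisible(NULL)
}

new_result_set <- function(matched, corpus) {
  matched <- sort(unique(as.integer(matched)))
  structure(list(
    matched = matched,
    total = length(matched),
    sample_ids = vapply(corpus[matched], function(r) r$sample_id, "")
  ), class = "bioscoop_resultset")
}

#' Evaluate a query over a record set
#'
#' Set-algebraic evaluation: each leaf term is matched against
#' per-field value columns extracted from the corpus, boolean nodes
#' combine the resulting index sets (intersection, union, complement
#' over the whole corpus for NOT).  Records lacking a queried field
#' never match a positive term but do match its negation.
#'
#' @param query A `bioscoop_query` from [parse_query()], or a query
#'   string (parsed on the fly).
#' @param corpus List of valid records.
#' @return A `bioscoop_resultset`: `matched` (sorted 1-based record
#'   indices), `total`, and the matched `sample_ids`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_records = 20, seed = 1))
#' evaluate_query("bmi:[18 TO 23]", cohort)$total
#' @export
evaluate_query <- function(query, corpus) {
  if (is.character(query)) query <- parse_query(query)
  stopifnot(inherits(query, "bioscoop_query"))
  check_known_fields(query)
  views <- lapply(corpus, flatten_record)
  idx <- eval_node_sets(query, views)
  new_result_set(idx, corpus)
}

eval_node_sets <- function(node, views) {
  n <- length(views)
  if (node$kind == "bool") {
    sets <- lapply(node$children, eval_node_sets, views = views)
    return(switch(node$op,
      AND = Reduce(intersect, sets),
      OR = sort(unique(unlist(sets))),
      NOT = setdiff(seq_len(n), sets[[1L]])
    ))
  }
  # leaf: column of field values across the corpus
  which(vapply(views, function(v) leaf_matches_column(node, v[[node$field]]),
               TRUE))
}

# vectorized leaf matcher used by the set-algebra route
leaf_matches_column <- function(node, values) {
  if (is.null(values) || length(values) == 0L) return(FALSE)
  type <- .QUERY_FIELDS[[node$field]]
  if (node$kind %in% c("field", "phrase")) {
    if (type == "number") {
      q <- suppressWarnings(as.numeric(node$value))
      if (is.na(q)) return(FALSE)
      return(any(as.numeric(values) == q))
    }
    return(any(tolower(as.character(values)) == tolower(node$value)))
  }
  # range
  if (type == "number") {
    v <- as.numeric(values)
    lo <- if (is.null(node$lo)) -Inf else as.numeric(node$lo)
    hi <- if (is.null(node$hi)) Inf else as.numeric(node$hi)
    if (is.na(lo) || is.na(hi)) {
      stop(sprintf("query error: non-numeric bound for numeric field '%s'",
                   node$field), call. = FALSE)
    }
    return(any(v >= lo & v <= hi))
  }
  v <- tolower(as.character(values))
  ok <- rep(TRUE, length(v))
  if (!is.null(node$lo)) ok <- ok & v >= tolower(node$lo)
  if (!is.null(node$hi)) ok <- ok & v <= tolower(node$hi)
  any(ok)
}

#' Reference query evaluator (independent oracle)
#'
#' Evaluates the query as a per-record recursive truth predicate, with
#' no set algebra and its own scalar comparison code.  Exists solely to
#' cross-check [evaluate_query()]; the two must agree on every
#' (query, corpus) pair.
#'
#' @inheritParams evaluate_query
#' @return A `bioscoop_resultset` identical to [evaluate_query()]'s.
#' @export
brute_force_filter <- function(query, corpus) {
  if (is.character(query)) query <- parse_query(query)
  stopifnot(inherits(query, "bioscoop_query"))
  check_known_fields(query)
  matched <- integer()
  for (i in seq_along(corpus)) {
    if (record_satisfies(query, flatten_record(corpus[[i]]))) {
      matched <- c(matched, i)
    }
  }
  new_result_set(matched, corpus)
}

# scalar truth evaluation for one record view (oracle route)
record_satisfies <- function(node, view) {
  if (node$kind == "bool") {
    hits <- vapply(node$children, record_satisfies, TRUE, view = view)
    return(switch(node$op,
                  AND = all(hits), OR = any(hits), NOT = !hits[[1L]]))
  }
  values <- view[[node$field]]
  if (is.null(values)) return(FALSE)
  numeric_field <- identical(.QUERY_FIELDS[[node$field]], "number")
  for (v in values) {
    hit <- if (node$kind %in% c("field", "phrase")) {
      if (numeric_field) {
        q <- suppressWarnings(as.numeric(node$value))
        !is.na(q) && isTRUE(as.numeric(v) == q)
      } else {
        tolower(as.character(v)) == tolower(node$value)
      }
    } else if (numeric_field) {
      x <- as.numeric(v)
      lo_ok <- is.null(node$lo) || x >= as.numeric(node$lo)
      hi_ok <- is.null(node$hi) || x <= as.numeric(node$hi)
      if ((!is.null(node$lo) && is.na(as.numeric(node$lo))) ||
          (!is.null(node$hi) && is.na(as.numeric(node$hi)))) {
        stop(sprintf("query error: non-numeric bound for numeric field '%s'",
                     node$field), call. = FALSE)
      }
      lo_ok && hi_ok
    } else {
      x <- tolower(as.character(v))
      (is.null(node$lo) || x >= tolower(node$lo)) &&
        (is.null(node$hi) || x <= tolower(node$hi))
    }
    if (isTRUE(hit)) return(TRUE)
  }
  FALSE
}

#' @export
print.bioscoop_resultset <- function(x, ...) {
  cat(sprintf("Query result: %d record(s) matched\n", x$total))
  if (x$total > 0L) {
    cat("sample IDs:", paste(x$sample_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a result set as JSON
#'
#' @param result A `bioscoop_resultset`.
#' @return A JSON string `{"total": n, "matchedSampleIds": [...]}`.
#' @export
result_set_json <- function(result) {
  stopifnot(inherits(result, "bioscoop_resultset"))
  jsonlite::toJSON(list(total = result$total,
                        matchedSampleIds = as.list(result$sample_ids)),
                   auto_unbox = TRUE)
}

# --- random query generation (for the oracle-equivalence property) ----------

# Draw a random query AST over the registry fields, mixing values taken
# from the corpus with fresh ones.  Used by the test-suite and the
# acceptance script; consumes the current RNG stream.
random_query_ast <- function(views, depth = 2L) {
  pick_leaf <- function() {
    field <- draw(names(.QUERY_FIELDS))
    type <- .QUERY_FIELDS[[field]]
    pool <- unlist(lapply(views, function(v) v[[field]]), use.names = FALSE)
    if (type == "number") {
      centre <- if (length(pool) && runif(1) < 0.8) {
        as.numeric(draw(pool))
      } else runif(1, 0, 200)
      if (runif(1) < 0.5) {
        lo <- round(centre - runif(1, 0, 30), 2)
        hi <- round(centre + runif(1, 0, 30), 2)
        range_term(field,
                   if (runif(1) < 0.15) NULL else as.character(lo),
                   if (runif(1) < 0.15) NULL else as.character(hi))
      } else {
        field_term(field, as.character(if (runif(1) < 0.7 && length(pool)) {
          draw(pool)
        } else round(centre, 2)))
      }
    } else {
      value <- if (length(pool) && runif(1) < 0.8) {
        as.character(draw(pool))
      } else draw(c("male", "xyz", "Gdansk, Poland", "A+", "2000-01-01"))
      if (runif(1) < 0.3) {
        phrase_term(field, value)
      } else if (runif(1) < 0.25 && .QUERY_FIELDS[[field]] == "date") {
        range_term(field, "1950-01-01", value)
      } else {
        # bare terms cannot carry spaces; quote them as phrases instead
        if (grepl("\\s", value)) phrase_term(field, value)
        else field_term(field, value)
      }
    }
  }
  build <- function(d) {
    r <- runif(1)
    if (d <= 0L || r < 0.45) {
      pick_leaf()
    } else if (r < 0.6) {
      bool_node("NOT", list(build(d - 1L)))
    } else {
      op <- if (runif(1) < 0.5) "AND" else "OR"
      k <- sample.int(2L, 1L) + 1L
      bool_node(op, lapply(seq_len(k), function(...) build(d - 1L)))
    }
  }
  build(depth)
}
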