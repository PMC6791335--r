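# helper: a tiny corpus with known bmi values and no other anthropometry,
# plus one record without any bmi at all
bmi_corpus <- function(values = c(17, 20, 25), with_missing = FALSE) {
  recs <- lapply(seq_along(values), function(i) {
    make_valid_record(donor_id = sprintf("DON-%04d", i),
                      sample_id = sprintf("SAM-%04d", i),
                      height_cm = NULL, weight_kg = NULL, waist_cm = NULL,
                      hip_cm = NULL, whr = NULL, ci = NULL, extras = NULL,
                      bmi = values[i])
  })
  if (with_missing) {
    recs <- c(recs, list(make_valid_record(
      donor_id = "DON-9999", sample_id = "SAM-9999", height_cm = NULL,
      weight_kg = NULL, waist_cm = NULL, hip_cm = NULL, whr = NULL,
      bmi = NULL, ci = NULL, extras = NULL)))
  }
  recs
}

test_that("the stock query forms parse to the expected trees", {
  q1 <- parse_query("gender:male")
  expect_identical(q1$kind, "field")
  expect_identical(q1$field, "sex")  # gender resolves to the donor sex field
  expect_identical(q1$value, "male")

  q2 <- parse_query('birthPlace:"Gdansk, Poland"')
  expect_identical(q2$kind, "phrase")
  expect_identical(q2$field, "birthPlace")
  expect_identical(q2$value, "Gdansk, Poland")

  q3 <- parse_query("bmi:[18 TO 23]")
  expect_identical(q3$kind, "range")
  expect_identical(c(q3$lo, q3$hi), c("18", "23"))

  q4 <- parse_query("gender:male AND bmi:[18 TO 23]")
  expect_identical(q4$kind, "bool")
  expect_identical(q4$op, "AND")
  expect_identical(vapply(q4$children, `[[`, "", "kind"),
                   c("field", "range"))

  q5 <- parse_query("NOT (sex:male OR sex:female)")
  expect_identical(q5$op, "NOT")
  expect_identical(q5$children[[1]]$op, "OR")

  # open bounds and left association
  q6 <- parse_query("bmi:[* TO 23]")
  expect_null(q6$lo)
  q7 <- parse_query("sex:male AND sex:male AND sex:female")
  expect_length(q7$children, 3L)
})

test_that("malformed queries fail with positioned parse errors", {
  bad <- c(
    "bmi:[23 TO 18]",          # inverted numeric bounds
    "bmi:[18 TO",              # unbalanced bracket
    'birthPlace:"Gdansk',      # unbalanced quote
    "gender male",             # missing colon
    "sex:male AND",            # dangling operator
    "sex:male AND OR sex:female",
    "sex:male AND bmi:[18 TO 23] OR sex:female",  # mixed ops, no parens
    "bmi:{18 TO 23}",          # exclusive ranges reserved
    "(sex:male",               # unbalanced paren
    "sex:male)",
    "sex:",
    ""
  )
  for (q in bad) {
    err <- tryCatch(parse_query(q), error = identity)
    expect_s3_class(err, "bioscoop_parse_error")
    expect_match(conditionMessage(err), "position [0-9]+", info = q)
  }
  # the mixed-operator error asks for parentheses
  err <- tryCatch(parse_query("a:1 AND b:2 OR c:3"), error = identity)
  expect_match(conditionMessage(err), "parentheses")
})

test_that("flattening exposes aliases, multi-valued codes and absent fields", {
  rec <- make_valid_record(
    medical_events = list(
      list(icd10_code = "E11.9", event_type = "disease"),
      list(icd10_code = "I10", event_type = "procedure")))
  view <- flatten_record(rec)
  expect_identical(view$gender, "male")
  expect_identical(view$sex, "male")
  expect_identical(view$birthPlace, "Gdansk, Poland")
  expect_identical(view$icd10, c("E11.9", "I10"))
  expect_length(view$eventType, 2L)

  bare <- make_valid_record(height_cm = NULL, weight_kg = NULL,
                            waist_cm = NULL, hip_cm = NULL, whr = NULL,
                            bmi = NULL, ci = NULL, extras = NULL)
  expect_null(flatten_record(bare)$bmi)
})

test_that("range evaluation is inclusive with open-bound and absent-field semantics", {
  corpus <- bmi_corpus(c(17, 20, 25), with_missing = TRUE)
  expect_identical(evaluate_query("bmi:[18 TO 23]", corpus)$matched, 2L)
  # inclusive endpoints: [x TO x] hits exactly the records equal to x
  expect_identical(evaluate_query("bmi:[20 TO 20]", corpus)$matched, 2L)
  expect_identical(evaluate_query("bmi:[17 TO 25]", corpus)$matched, 1:3)
  # open range matches every record possessing the field
  expect_identical(evaluate_query("bmi:[* TO *]", corpus)$matched, 1:3)
  # absent fields never match a positive term, but do match NOT
  expect_identical(evaluate_query("NOT bmi:[* TO *]", corpus)$matched, 4L)
})

test_that("boolean semantics are set algebra over the corpus", {
  corpus <- c(bmi_corpus(c(17, 20, 25), with_missing = TRUE),
              list(make_valid_record(donor_id = "DON-0005",
                                     sample_id = "SAM-0005",
                                     sex = "female")))
  all_ids <- seq_along(corpus)
  # excluded middle over complement semantics: the full corpus
  expect_identical(
    evaluate_query("(NOT gender:male) OR gender:male", corpus)$matched,
    all_ids)
  # q AND q == q; NOT NOT q == q; De Morgan
  q <- "gender:male AND gender:male"
  expect_identical(evaluate_query(q, corpus)$matched,
                   evaluate_query("gender:male", corpus)$matched)
  expect_identical(evaluate_query("NOT (NOT gender:male)", corpus)$matched,
                   evaluate_query("gender:male", corpus)$matched)
  expect_identical(
    evaluate_query("NOT (gender:male OR bmi:[18 TO 23])", corpus)$matched,
    evaluate_query("(NOT gender:male) AND (NOT bmi:[18 TO 23])",
                   corpus)$matched)
})

test_that("matching is case-insensitive full-string", {
  corpus <- list(make_valid_record())
  expect_identical(evaluate_query("sex:MALE", corpus)$total, 1L)
  expect_identical(evaluate_query('birthPlace:"gdansk, poland"', corpus)$total,
                   1L)
  # substring is not a match
  expect_identical(evaluate_query('birthPlace:"Gdansk"', corpus)$total, 0L)
})

test_that("unknown fields are loud query errors", {
  corpus <- list(make_valid_record())
  expect_error(evaluate_query("bmii:[18 TO 23]", corpus), "unknown field")
  expect_error(brute_force_filter("typo:male", corpus), "unknown field")
})

test_that("result sets are sorted, deduplicated and serializable", {
  corpus <- bmi_corpus(c(19, 21, 22))
  res <- evaluate_query("bmi:[18 TO 23]", corpus)
  expect_identical(res$matched, sort(unique(res$matched)))
  expect_identical(res$total, length(res$matched))
  js <- jsonlite::fromJSON(result_set_json(res))
  expect_identical(js$total, 3L)
  expect_identical(js$matchedSampleIds,
                   c("SAM-0001", "SAM-0002", "SAM-0003"))

  empty <- brute_force_filter("sex:male", list())
  expect_identical(empty$total, 0L)
  expect_length(empty$matched, 0L)
})

test_that("widening a range never shrinks the result set", {
  cohort <- generate_cohort(cohort_config(n_records = 50, seed = 17))
  bounds <- list(c(20, 22), c(18, 25), c(15, 35), c(-Inf, Inf))
  last <- -1L
  for (b in bounds) {
    q <- if (is.infinite(b[1])) "bmi:[* TO *]" else {
      sprintf("bmi:[%g TO %g]", b[1], b[2])
    }
    n <- evaluate_query(q, cohort)$total
    expect_gte(n, last)
    last <- n
  }
})

test_that("set-algebra evaluation agrees with the per-record oracle on random queries", {
  withr::with_seed(4242, {
    for (rep in 1:2) {
      cohort <- generate_cohort(cohort_config(n_records = 25,
                                              seed = 100 + rep))
      views <- lapply(cohort, flatten_record)
      for (k in 1:50) {
        ast <- bioscoop:::random_query_ast(views)
        expect_identical(evaluate_query(ast, cohort)$matched,
                         brute_force_filter(ast, cohort)$matched,
                         info = bioscoop:::deparse_query(ast))
      }
    }
  })
})
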