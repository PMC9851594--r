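test_that("a two-category schema parses field by field", {
  s <- fixture_pv()
  expect_s3_class(s, "smw_schema")
  expect_equal(n_errors(validate_schema(s)), 0)
  expect_length(s$categories, 2)

  pat <- s$categories[[1]]
  expect_equal(pat$name, "Patients")
  expect_null(pat$connection)
  expect_length(pat$properties, 1)
  age <- pat$properties[[1]]
  expect_equal(age$label, "Age")
  expect_equal(age$type, "NUMBER")
  expect_equal(age$constraint$kind, "RANGE")
  expect_equal(age$constraint$min, 0)
  expect_equal(age$constraint$max, 120)

  vis <- s$categories[[2]]
  expect_equal(vis$connection, list(property = "Has Patient",
                                    target = "Patients"))
  tmp <- vis$properties[[1]]
  expect_equal(tmp$label, "Temperature")
  expect_equal(tmp$unit, "°C")
  expect_equal(tmp$constraint$min, 30)
  expect_equal(tmp$constraint$max, 45)
})

test_that("a header-only file yields zero categories and a validation error", {
  s <- parse_schema("label\ttype\tconstraint\tunit\tnote")
  expect_length(s$categories, 0)
  d <- validate_schema(s)
  expect_gte(n_errors(d), 1)
  expect_match(d$message[d$severity == "ERROR"][1], "at least one")
})

test_that("complex clinical properties carry their aspect decomposition", {
  s <- fixture_audiology()
  expect_equal(n_errors(validate_schema(s)), 0)
  p <- s$categories[[2]]$properties[[1]]
  expect_equal(p$label, AUDIOLOGY_LABEL)
  expect_equal(p$type, "NUMBER")
  expect_length(p$aspects, 4)
  expect_equal(p$aspects[["laterality"]], "left")
  expect_equal(p$aspects[["device"]], "intracochlear")
})

test_that("aspect relations outside the vocabulary are rejected", {
  s <- parse_schema(paste(
    "!category\tPatients",
    "Weight\tnumber\t\t\t\tflavour=strange", sep = "\n"))
  d <- schema_diagnostics(s)
  expect_gte(n_errors(d), 1)
  expect_match(d$message[1], "vocabulary")
  # ... but custom vocabularies are accepted
  s2 <- parse_schema(paste(
    "!category\tPatients",
    "Weight\tnumber\t\t\t\tflavour=strange", sep = "\n"),
    aspect_vocab = "flavour")
  expect_equal(n_errors(schema_diagnostics(s2)), 0)
})

test_that("semantic invariants produce line-addressed errors", {
  # reversed range
  s <- parse_schema(paste(
    "!category\tPatients",
    "Age\tnumber\t45:30", sep = "\n"))
  d <- validate_schema(s)
  expect_equal(n_errors(d), 1)
  expect_match(diag_msg(d), "range")
  expect_match(diag_msg(d), "Age")
  expect_equal(d$line[d$severity == "ERROR"], 2L)

  # unresolved connection target
  s <- parse_schema(paste(
    "!category\tVisits\tconnection=Has Patient->Patientz",
    "Temperature\tnumber", sep = "\n"))
  d <- validate_schema(s)
  expect_equal(n_errors(d), 1)
  expect_match(diag_msg(d), "unresolved reference")

  # duplicate property labels and duplicate categories
  s <- parse_schema(paste(
    "!category\tPatients", "Age\tnumber", "Age\tnumber",
    "!category\tPatients", sep = "\n"))
  d <- validate_schema(s)
  expect_gte(n_errors(d), 2)

  # subclass cycle
  s <- parse_schema(paste(
    "!category\tA\tparent=B", "!category\tB\tparent=A", sep = "\n"))
  d <- validate_schema(s)
  expect_match(paste(diag_msg(d), collapse = " "), "cycle")

  # a valid schema validates cleanly and is not mutated
  s <- fixture_pv()
  before <- serialize_schema(s)
  expect_equal(nrow(validate_schema(s)), 0)
  expect_identical(serialize_schema(s), before)
})

test_that("unknown type keywords and malformed directives are diagnosed", {
  s <- parse_schema(paste(
    "!category\tPatients",
    "Age\tnumbr", sep = "\n"))
  expect_match(diag_msg(schema_diagnostics(s)), "unknown type")

  s <- parse_schema(paste(
    "!categoree\tPatients", sep = "\n"))
  expect_match(diag_msg(schema_diagnostics(s)), "unknown directive")

  s <- parse_schema("Age\tnumber")
  expect_match(diag_msg(schema_diagnostics(s)), "before any !category")
})

test_that("page-title normalization follows the wiki rules and is idempotent", {
  expect_equal(property_page_name("has  temperature "), "Has temperature")
  expect_equal(property_page_name("Age"), "Age")
  expect_equal(property_page_name("BMI [kg/m2]"), "BMI kg/m2")
  expect_error(property_page_name(""), "empty")
  expect_error(property_page_name("[]{}"), "empty")

  set.seed(7)
  for (k in 1:200) {
    raw <- rawToChar(as.raw(sample(32:126, sample(1:30, 1), replace = TRUE)))
    t1 <- tryCatch(property_page_name(raw), error = function(e) NULL)
    if (is.null(t1)) next
    expect_identical(property_page_name(t1), t1)
    expect_false(grepl("[][#<>|{}]", t1))
    expect_equal(substring(t1, 1, 1), toupper(substring(t1, 1, 1)))
  }
})

test_that("parsing is total over arbitrary byte strings", {
  set.seed(11)
  for (k in 1:150) {
    bytes <- as.raw(sample(c(9L, 10L, 33L:126L, 195L), sample(0:80, 1),
                           replace = TRUE))
    txt <- suppressWarnings(rawToChar(bytes))
    expect_no_error({
      s <- parse_schema(txt)
      validate_schema(s)
    })
  }
})

test_that("serialize -> parse round-trips the schema", {
  for (s in list(fixture_pv(), fixture_covid(), fixture_audiology())) {
    s2 <- parse_schema(serialize_schema(s))
    expect_true(schema_equal(s, s2))
    expect_identical(serialize_schema(s2), serialize_schema(s))
  }
  set.seed(23)
  for (k in 1:25) {
    s <- random_schema()
    expect_equal(n_errors(validate_schema(s)), 0)
    expect_true(schema_equal(s, parse_schema(serialize_schema(s))))
  }
})

test_that("every reference in a valid random schema resolves", {
  set.seed(31)
  for (k in 1:20) {
    s <- random_schema()
    cats <- vapply(s$categories, `[[`, character(1), "name")
    for (c in s$categories) {
      if (!is.na(c$parent)) expect_true(c$parent %in% cats)
      if (!is.null(c$connection)) expect_true(c$connection$target %in% cats)
      for (p in c$properties)
        if (p$constraint$kind == "TARGET")
          expect_true(p$constraint$target %in% cats)
    }
  }
})

test_that("the category graph mirrors connections and page properties", {
  g <- schema_graph(fixture_pv())
  expect_equal(g$nodes, c("Patients", "Visits"))
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$from, "Visits")
  expect_equal(g$edges$to, "Patients")
  expect_equal(g$edges$property, "Has Patient")

  # no connections -> edgeless graph
  g0 <- schema_graph(parse_schema("!category\tPatients\nAge\tnumber"))
  expect_equal(nrow(g0$edges), 0)

  # three-category chain A <- B <- C: two edges, path length 2 end to end
  s3 <- graph_schema(c(0L, 1L, 2L))
  g3 <- schema_graph(s3)
  expect_equal(nrow(g3$edges), 2)
  ch <- resolve_chain(g3, "Cat1", "Prop 3")
  expect_equal(nrow(ch), 2)
  expect_equal(oracle_shortest(c(0L, 1L, 2L), 1L, 3L), 2)
})
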