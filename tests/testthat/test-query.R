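test_that("chains resolve through inverse connection steps", {
  s <- fixture_pv()
  g <- schema_graph(s)
  # Patients asking for the visits' temperature: one inverse step
  ch <- resolve_chain(g, "Patients", "Temperature")
  expect_equal(nrow(ch), 1)
  expect_equal(ch$direction, "INVERSE")
  expect_equal(render_chain(ch), "-Has Patient")
  # forward direction from the visit to its patient's age
  expect_equal(render_chain(resolve_chain(g, "Visits", "Age")), "Has Patient")
  # local property: empty chain
  expect_equal(nrow(resolve_chain(g, "Patients", "Age")), 0)
  # chains re-parse from their rendering
  expect_equal(parse_chain("-Has Patient.Has Centre")$direction,
               c("INVERSE", "FORWARD"))
  expect_error(resolve_chain(g, "Patients", "Nope"), "no category declares")
})

test_that("equidistant owners fail loudly; equal paths break ties predictably", {
  # two child categories both declare "Score", one step from Patients
  s <- parse_schema(paste(
    "!category\tPatients", "Age\tnumber",
    "!category\tVisits\tconnection=Has Patient->Patients", "Score\tnumber",
    "!category\tExams\tconnection=Has Subject->Patients", "Score\tnumber",
    sep = "\n"))
  g <- schema_graph(s)
  expect_error(resolve_chain(g, "Patients", "Score"),
               "ambiguous.*Exams.*Visits")

  # two parallel connections to the same category: deterministic tie-break
  s2 <- parse_schema(paste(
    "!category\tPatients", "Age\tnumber",
    "!category\tTransfusions\tconnection=Donor->Patients",
    "Volume\tnumber", sep = "\n"))
  # add a second edge by a page-typed property
  s2 <- parse_schema(paste(
    "!category\tPatients", "Age\tnumber",
    "!category\tTransfusions\tconnection=Donor->Patients",
    "Volume\tnumber",
    "Recipient\tpage\t->Patients", sep = "\n"))
  g2 <- schema_graph(s2)
  expect_warning(ch <- resolve_chain(g2, "Patients", "Volume"),
                 "equally short")
  expect_equal(render_chain(ch), "-Donor")  # '-Donor' < '-Recipient'
  expect_warning(ch2 <- resolve_chain(g2, "Patients", "Volume"))
  expect_identical(render_chain(ch2), render_chain(ch))
})

test_that("resolved path lengths match exhaustive enumeration on random graphs", {
  set.seed(71)
  for (k in 1:40) {
    n <- sample(3:8, 1)
    parents <- integer(n)
    for (i in 2:n) parents[i] <- sample(0:(i - 1), 1)
    s <- graph_schema(parents)
    g <- schema_graph(s)
    from <- sample(n, 1); to <- sample(n, 1)
    want <- oracle_shortest(parents, from, to)
    if (from == to) {
      expect_equal(nrow(resolve_chain(g, sprintf("Cat%d", from),
                                      sprintf("Prop %d", to))), 0)
    } else if (is.finite(want)) {
      ch <- suppressWarnings(resolve_chain(g, sprintf("Cat%d", from),
                                           sprintf("Prop %d", to)))
      expect_equal(nrow(ch), want)
      rendered <- render_chain(ch)
      expect_equal(lengths(regmatches(rendered,
                                      gregexpr("(^|\\.)-", rendered))),
                   sum(ch$direction == "INVERSE"))
    } else {
      expect_error(resolve_chain(g, sprintf("Cat%d", from),
                                 sprintf("Prop %d", to)), "not reachable")
    }
  }
})

test_that("ask queries render the documented dialect", {
  s <- fixture_pv()
  q <- ask_query(s, "Visits",
                 conditions = list(list(property = "Temperature",
                                        comparator = "GT", value = 37)),
                 printouts = "Temperature")
  expect_identical(build_ask(q, s),
                   "{{#ask: [[Category:Visits]] [[Temperature::>37]] |?Temperature}}")
  expect_identical(build_ask(ask_query(s, "Visits"), s),
                   "{{#ask: [[Category:Visits]]}}")
  # cross-category printout gets the inverse chain
  q2 <- ask_query(s, "Patients", printouts = c("Age", "Temperature"))
  expect_identical(build_ask(q2, s),
                   "{{#ask: [[Category:Patients]] |?Age |?-Has Patient.Temperature}}")
  # inclusive comparators render as two-character forms
  q3 <- ask_query(s, "Visits",
                  conditions = list(list(property = "Temperature",
                                         comparator = "GE", value = 37.5)))
  expect_match(build_ask(q3, s), "[[Temperature::>=37.5]]", fixed = TRUE)
  expect_error(ask_query(s, "Visits",
                         conditions = list(list(property = "Temperature",
                                                comparator = "XX", value = 1))),
               "comparator")
  # order comparators are refused on unordered types
  s2 <- fixture_covid()
  expect_error(ask_query(s2, "Patients",
                         conditions = list(list(property = "Sex",
                                                comparator = "GT",
                                                value = "M"))),
               "number or date")
})

test_that("query text is stable and survives a print/parse cycle", {
  s <- fixture_covid()
  rs <- generate_records(s, gen_config(n_parents = 15, seed = 4))
  set.seed(83)
  for (k in 1:10) {
    cmp <- sample(c("GT", "GE", "LT", "LE"), 1)
    val <- round(runif(1, 30, 45), 1)
    q <- ask_query(s, sample(c("Patients", "Samplings"), 1),
                   conditions = list(list(property = "Temperature",
                                          comparator = cmp, value = val)),
                   printouts = sample(c("Temperature", "Age", "Result"),
                                      sample(0:3, 1)))
    txt <- build_ask(q, s)
    expect_identical(build_ask(q, s), txt)
    q2 <- parse_ask(txt, s)
    expect_identical(build_ask(q2, s), txt)
    expect_identical(evaluate_ask(q2, rs), evaluate_ask(q, rs))
  }
})

test_that("the evaluator agrees with a direct brute-force filter", {
  s <- fixture_pv()
  rs <- generate_records(s, gen_config(n_parents = 30, seed = 5,
                                       missing_rate = 0.2))
  q <- ask_query(s, "Visits",
                 conditions = list(list(property = "Temperature",
                                        comparator = "GT", value = 37)),
                 printouts = "Temperature")
  res <- evaluate_ask(q, rs)
  want <- Filter(function(r) r$category == "Visits" &&
                   !is.null(r$values$Temperature) &&
                   r$values$Temperature > 37, rs$records)
  expect_equal(nrow(res), length(want))
  expect_setequal(res$Entity, vapply(want, `[[`, character(1), "title"))
  expect_equal(sort(as.numeric(res[["?Temperature"]])),
               sort(vapply(want, function(r) r$values$Temperature,
                           numeric(1))))

  # chained condition: patients having a hot visit
  qp <- ask_query(s, "Patients",
                  conditions = list(list(property = "Temperature",
                                         comparator = "GT", value = 37)))
  resp <- evaluate_ask(qp, rs)
  want_titles <- unique(vapply(want, `[[`, character(1), "parent_title"))
  expect_setequal(resp$Entity, want_titles)

  # empty record set -> empty table
  empty <- generate_records(s, gen_config(n_parents = 0))
  expect_equal(nrow(evaluate_ask(q, empty)), 0)
})

test_that("EQ on the explicit NA selects NA records, not missing ones", {
  s <- fixture_covid()
  rs <- generate_records(s, gen_config(n_parents = 40, seed = 6,
                                       missing_rate = 0.3))
  q <- ask_query(s, "Patients",
                 conditions = list(list(property = "Smoker",
                                        comparator = "EQ", value = "NA")))
  res <- evaluate_ask(q, rs)
  want <- Filter(function(r) r$category == "Patients" &&
                   identical(r$values$Smoker, "NA"), rs$records)
  miss <- Filter(function(r) r$category == "Patients" &&
                   is.null(r$values$Smoker), rs$records)
  expect_gt(length(want), 0)
  expect_gt(length(miss), 0)
  expect_setequal(res$Entity, vapply(want, `[[`, character(1), "title"))
})
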