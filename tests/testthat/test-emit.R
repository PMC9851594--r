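test_that("property pages carry the type map and domain annotations", {
  s <- fixture_pv()
  tmp <- s$categories[[2]]$properties[[1]]
  pg <- emit_property_page(tmp)
  expect_equal(pg$title, "Temperature")
  expect_equal(pg$ns, 102L)
  expect_equal(lengths(regmatches(pg$text,
                                  gregexpr("\\[\\[Has type::", pg$text))), 1L)
  expect_match(pg$text, "[[Has type::Number]]", fixed = TRUE)
  expect_match(pg$text, "°C", fixed = TRUE)

  tri <- parse_schema(
    "!category\tPatients\nSmoker\ttristate")$categories[[1]]$properties[[1]]
  pg <- emit_property_page(tri)
  expect_match(pg$text, "[[Has type::Text]]", fixed = TRUE)
  av <- regmatches(pg$text, gregexpr("\\[\\[Allows value::[^]]+\\]\\]",
                                     pg$text))[[1]]
  expect_equal(av, sprintf("[[Allows value::%s]]", c("Yes", "No", "NA")))

  audio <- fixture_audiology()$categories[[2]]$properties[[1]]
  pg <- emit_property_page(audio)
  expect_match(pg$text, "[[laterality::left]]", fixed = TRUE)
  expect_match(pg$text, "[[device::intracochlear]]", fixed = TRUE)
})

test_that("templates annotate guardedly and end with the category tag", {
  s <- fixture_pv()
  tpl <- emit_template(s$categories[[1]])
  expect_equal(tpl$ns, 10L)
  expect_match(tpl$text,
               "{{#if:{{{Age|}}}|[[Age::{{{Age}}}]]|}}", fixed = TRUE)
  expect_match(tpl$text, "[[Category:Patients]]</includeonly>", fixed = TRUE)
  # exactly one data row in the table body
  expect_equal(lengths(regmatches(tpl$text, gregexpr("\\{\\{#if:", tpl$text))),
               1L)

  vis <- emit_template(s$categories[[2]])
  expect_match(vis$text,
               "{{#if:{{{Has Patient|}}}|[[Has Patient::{{{Has Patient}}}]]|}}",
               fixed = TRUE)

  empty <- emit_template(parse_schema("!category\tThings")$categories[[1]])
  expect_match(empty$text,
               "<includeonly>[[Category:Things]]</includeonly>", fixed = TRUE)
})

test_that("forms choose input controls by property type", {
  s <- fixture_covid()
  f <- emit_form(s$categories[[1]])
  expect_equal(f$ns, 106L)
  expect_match(f$text, "{{{field|Age|input type=text|size=10|min=0|max=120}}}",
               fixed = TRUE)
  expect_match(f$text,
               "{{{field|Main symptom|input type=dropdown|values=fever,cough,anosmia,dyspnea,none}}}",
               fixed = TRUE)
  expect_match(f$text, "{{{field|Smoker|input type=dropdown|values=Yes,No,NA}}}",
               fixed = TRUE)
  expect_match(f$text, "{{{field|Hospitalized|input type=checkbox}}}",
               fixed = TRUE)
  expect_match(f$text, "{{{field|Onset date|input type=datepicker}}}",
               fixed = TRUE)

  f2 <- emit_form(s$categories[[2]])
  expect_match(f2$text,
               "{{{field|Has Patient|input type=combobox|values from category=Patients}}}",
               fixed = TRUE)

  fe <- emit_form(parse_schema("!category\tThings")$categories[[1]])
  expect_match(fe$text, "{{{standard input|save}}}", fixed = TRUE)
  expect_false(grepl("{{{field|", fe$text, fixed = TRUE))
})

test_that("category pages declare form, parent and drilldown filters", {
  s <- fixture_covid()
  cp <- emit_category_page(s$categories[[2]])
  expect_equal(cp$ns, 14L)
  expect_match(cp$text, "{{#default_form:Samplings}}", fixed = TRUE)
  expect_match(cp$text, "Result (property=Result, group=Sampling)",
               fixed = TRUE)
  expect_match(cp$text, "Home isolation (property=Home isolation",
               fixed = TRUE)
  # every domain property is a filter
  expect_match(cp$text, "Temperature (property=Temperature", fixed = TRUE)

  sub <- parse_schema(paste("!category\tA", "!category\tB\tparent=A",
                            sep = "\n"))
  expect_false(grepl("[[Category:", emit_category_page(sub$categories[[1]])$text,
                     fixed = TRUE))
  expect_match(emit_category_page(sub$categories[[2]])$text, "[[Category:A]]",
               fixed = TRUE)
})

test_that("a compiled site has the predicted page inventory and closure", {
  s <- fixture_pv()
  doc <- emit_site(s)
  # 1 main + 2 x (template, form, category) + Age, Temperature, Has Patient
  expect_length(doc$pages, 10)
  expect_equal(expected_page_count(s), 10)
  expect_equal(check_property_closure(doc), character(0))
  titles <- vapply(doc$pages, smwbuilder:::full_title, character(1))
  expect_true("Property:Has Patient" %in% titles)
  expect_equal(anyDuplicated(titles), 0)

  covid <- emit_site(fixture_covid())
  expect_length(covid$pages, expected_page_count(fixture_covid()))
  expect_equal(check_property_closure(covid), character(0))

  # aspect relations get property pages exactly once
  audio <- emit_site(fixture_audiology())
  t2 <- vapply(audio$pages, smwbuilder:::full_title, character(1))
  expect_equal(sum(t2 == "Property:Laterality"), 1)
  expect_equal(check_property_closure(audio), character(0))

  expect_error(emit_site(parse_schema("!category\tA\tparent=Zz")), "invalid")
})

test_that("page count formula and closure hold on random schemas", {
  set.seed(41)
  for (k in 1:15) {
    s <- random_schema()
    doc <- emit_site(s)
    expect_length(doc$pages, expected_page_count(s))
    expect_equal(check_property_closure(doc), character(0))
  }
})

test_that("doubling the categories doubles the per-category pages", {
  one <- parse_schema("!category\tA\nP1\tnumber")
  two <- parse_schema("!category\tA\nP1\tnumber\n!category\tB\nP2\tnumber")
  n1 <- length(emit_site(one)$pages)
  n2 <- length(emit_site(two)$pages)
  expect_equal(n2 - n1, 3 + 1)  # 3 category pages + 1 property page
})

test_that("serialization is well-formed, escaped and byte-deterministic", {
  s <- fixture_covid()
  doc <- emit_site(s)
  xml <- serialize_xml(doc)
  expect_identical(serialize_xml(emit_site(s)), xml)
  expect_equal(check_mediawiki_xml(xml), character(0))

  # special characters survive the XML layer
  pg <- smwbuilder:::new_wiki_page("Oddities", 0L,
                                   "a < b & c > d {{tpl|x=1}}")
  doc2 <- smwbuilder:::new_wiki_doc(list(pg))
  xml2_ <- serialize_xml(doc2)
  reread <- xml2::read_xml(xml2_)
  txt <- xml2::xml_text(xml2::xml_find_first(
    reread, "//d1:text", xml2::xml_ns(reread)))
  expect_identical(txt, "a < b & c > d {{tpl|x=1}}")
})

test_that("the structural validator rejects malformed documents", {
  xml <- serialize_xml(emit_site(fixture_pv()))
  expect_equal(check_mediawiki_xml(xml), character(0))

  expect_match(paste(check_mediawiki_xml("<mediawiki>"), collapse = " "),
               "not well-formed")
  expect_match(paste(check_mediawiki_xml("<mediawiki/>"), collapse = " "),
               "namespace")
  bad <- sub("text/x-wiki", "text/plain", xml, fixed = TRUE)
  expect_match(paste(check_mediawiki_xml(bad), collapse = " "),
               "text/x-wiki")
  bad2 <- sub('version="0.10"', 'version="0.9"', xml, fixed = TRUE)
  expect_match(paste(check_mediawiki_xml(bad2), collapse = " "), "version")
})

test_that("the Italian catalog localizes the generated boilerplate", {
  s <- fixture_pv()
  it <- emit_site(s, lang = "it")
  main <- it$pages[[1]]
  expect_match(main$text, "Benvenuti", fixed = TRUE)
  en <- emit_site(s, lang = "en")
  expect_match(en$pages[[1]]$text, "Welcome", fixed = TRUE)
  # an unknown language falls back to English rather than failing
  expect_match(emit_site(s, lang = "de")$pages[[1]]$text, "Welcome")
})
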