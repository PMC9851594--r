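#' MediaWiki namespaces used by generated sites
#' @format Named integer vector (`MAIN`, `TEMPLATE`, `CATEGORY`, `PROPERTY`,
#'   `FORM`).
#' @export
WIKI_NAMESPACES <- c(MAIN = 0L, TEMPLATE = 10L, CATEGORY = 14L,
                     PROPERTY = 102L, FORM = 106L)

NS_PREFIXES <- c("0" = "", "10" = "Template", "14" = "Category",
                 "102" = "Property", "106" = "Form")

new_wiki_page <- function(title, ns, text) {
  stopifnot(is_valid_title(title))
  structure(list(title = title, ns = as.integer(ns), text = text),
            class = "smw_wiki_page")
}

full_title <- function(page) {
  pre <- NS_PREFIXES[[as.character(page$ns)]]
  if (nzchar(pre)) paste0(pre, ":", page$title) else page$title
}

new_wiki_doc <- function(pages, sitename = "Wiki database", lang = "en",
                         timestamp = "2020-01-01T00:00:00Z") {
  keys <- vapply(pages, function(p) paste0(p$ns, ":", p$title), character(1))
  if (anyDuplicated(keys))
    stop("duplicate page titles: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  structure(list(pages = pages, sitename = sitename, lang = lang,
                 timestamp = timestamp,
                 generator = "smwbuilder 0.1.0"),
            class = "smw_wiki_doc")
}

#' @export
print.smw_wiki_doc <- function(x, ...) {
  cat(sprintf("<smw_wiki_doc> \"%s\": %d pages\n", x$sitename,
              length(x$pages)))
  for (p in x$pages) cat(sprintf("  [ns %3d] %s\n", p$ns, full_title(p)))
  invisible(x)
}

# --- property pages ---------------------------------------------------------

#' Emit the wiki page declaring one property
#'
#' The page carries exactly one `[[Has type::...]]` annotation, one
#' `[[Allows value::v]]` per categorical domain value in declared order, the
#' unit and help note as display text, and one `[[relation::value]]`
#' annotation per aspect pair (the relational decomposition of complex
#' clinical properties lives on the property page itself).
#'
#' @param p An `smw_property`.
#' @param strings UI string catalog from [ui_strings()].
#' @return An `smw_wiki_page` in the Property namespace.
#' @export
emit_property_page <- function(p, strings = ui_strings()) {
  smw_type <- SMW_TYPES[[p$type]]
  out <- sprintf("%s [[Has type::%s]].", strings[["prop_type"]], smw_type)
  if (nzchar(p$note)) out <- c(out, "", p$note)
  if (nzchar(p$unit))
    out <- c(out, "", sprintf("%s: %s", strings[["prop_unit"]], p$unit))
  if (p$constraint$kind == "DOMAIN") {
    out <- c(out, "", paste0(strings[["prop_allowed"]], ":"),
             sprintf("* [[Allows value::%s]]", p$constraint$values))
  }
  if (length(p$aspects)) {
    out <- c(out, "", paste0(strings[["prop_aspects"]], ":"),
             sprintf("* [[%s::%s]]", names(p$aspects), p$aspects))
  }
  new_wiki_page(p$page_name, WIKI_NAMESPACES[["PROPERTY"]],
                paste(out, collapse = "\n"))
}

# Synthetic specs for pages that exist only as link machinery.
connection_property_spec <- function(conn) {
  new_property(conn$property, "PAGE",
               new_constraint("TARGET", target = conn$target))
}

aspect_relation_spec <- function(relation) {
  new_property(relation, "TEXT")
}

# --- templates --------------------------------------------------------------

# [[Prop::value]] wrapped so an empty template parameter annotates nothing.
guarded_annotation <- function(prop_page_name) {
  sprintf("{{#if:{{{%s|}}}|[[%s::{{{%s}}}]]|}}",
          prop_page_name, prop_page_name, prop_page_name)
}

#' Emit the per-category template
#'
#' Renders a two-column (label, value) wikitable with group headings, one row
#' per property; every value cell attaches the semantic annotation through an
#' emptiness guard so unfilled parameters produce no annotation. When the
#' category has a one-to-many connection, the connection property is the
#' first row. The template ends with the category tag.
#'
#' @param c An `smw_category_spec`.
#' @param strings UI string catalog.
#' @return An `smw_wiki_page` in the Template namespace.
#' @export
emit_template <- function(c, strings = ui_strings()) {
  rows <- character()
  if (!is.null(c$connection)) {
    pn <- property_page_name(c$connection$property)
    rows <- c(rows, "|-", sprintf("! %s", pn),
              sprintf("| %s", guarded_annotation(pn)))
  }
  cur_group <- NULL
  for (p in c$properties) {
    if (!identical(p$group, cur_group)) {
      if (nzchar(p$group))
        rows <- c(rows, "|-", sprintf("! colspan=\"2\" | %s", p$group))
      cur_group <- p$group
    }
    rows <- c(rows, "|-", sprintf("! %s", p$label),
              sprintf("| %s", guarded_annotation(p$page_name)))
  }
  blurb <- sprintf(strings[["template_blurb"]], c$name, c$name, c$name)
  body <- if (length(rows))
    paste(c("{| class=\"wikitable\"", rows, "|}"), collapse = "\n")
  else ""
  text <- paste0(
    "<noinclude>\n", blurb, "\n</noinclude><includeonly>",
    body, if (nzchar(body)) "\n" else "",
    sprintf("[[Category:%s]]", c$name), "</includeonly>")
  new_wiki_page(property_page_name(c$name), WIKI_NAMESPACES[["TEMPLATE"]],
                text)
}

# --- forms ------------------------------------------------------------------

form_input_spec <- function(p) {
  switch(p$type,
    NUMBER = {
      s <- "input type=text|size=10"
      if (p$constraint$kind == "RANGE")
        s <- sprintf("%s|min=%s|max=%s", s, num_chr(p$constraint$min),
                     num_chr(p$constraint$max))
      s
    },
    DATE = "input type=datepicker",
    ENUM = ,
    TRISTATE = sprintf("input type=dropdown|values=%s",
                       paste(p$constraint$values, collapse = ",")),
    BOOLEAN = "input type=checkbox",
    PAGE = sprintf("input type=combobox|values from category=%s",
                   p$constraint$target),
    "input type=text"  # TEXT, URL, COORDINATES
  )
}

#' Emit the PageForms form for a category
#'
#' One field per property, grouped under the declared group headings; the
#' input control follows the property type (dropdowns listing the domain for
#' categorical and three-valued properties, a date picker for dates, a
#' min/max-bounded text input for constrained numbers, a checkbox for
#' booleans, category-restricted autocompletion for page links).
#'
#' @param c An `smw_category_spec`.
#' @param strings UI string catalog.
#' @return An `smw_wiki_page` in the Form namespace.
#' @export
emit_form <- function(c, strings = ui_strings()) {
  cname <- property_page_name(c$name)
  rows <- character()
  if (!is.null(c$connection)) {
    pn <- property_page_name(c$connection$property)
    rows <- c(rows, "|-", sprintf("! %s:", pn),
              sprintf("| {{{field|%s|input type=combobox|values from category=%s}}}",
                      pn, c$connection$target))
  }
  cur_group <- NULL
  for (p in c$properties) {
    if (!identical(p$group, cur_group)) {
      if (nzchar(p$group))
        rows <- c(rows, "|-", sprintf("! colspan=\"2\" | %s", p$group))
      cur_group <- p$group
    }
    rows <- c(rows, "|-", sprintf("! %s:", p$label),
              sprintf("| {{{field|%s|%s}}}", p$page_name, form_input_spec(p)))
  }
  body <- if (length(rows))
    paste(c("{| class=\"formtable\"", rows, "|}"), collapse = "\n")
  else NULL
  text <- paste(c(
    "<noinclude>",
    sprintf(strings[["form_blurb"]], c$name),
    sprintf("{{#forminput:form=%s}}", cname),
    "</noinclude><includeonly>",
    sprintf("{{{for template|%s}}}", cname),
    body,
    "{{{end template}}}",
    "{{{standard input|save}}} {{{standard input|preview}}} {{{standard input|cancel}}}",
    "</includeonly>"), collapse = "\n")
  new_wiki_page(cname, WIKI_NAMESPACES[["FORM"]], text)
}

# --- category pages ---------------------------------------------------------

drilldown_filterable <- function(p) {
  p$constraint$kind %in% c("DOMAIN", "RANGE") || p$type == "BOOLEAN"
}

#' Emit the category page
#'
#' Declares the default form, tags the parent category for subclasses, and
#' declares the multifaceted drilldown filters: every categorical,
#' three-valued, boolean or range-constrained property becomes a filter,
#' grouped by its property group.
#'
#' @param c An `smw_category_spec`.
#' @param strings UI string catalog.
#' @return An `smw_wiki_page` in the Category namespace.
#' @export
emit_category_page <- function(c, strings = ui_strings()) {
  cname <- property_page_name(c$name)
  out <- c(sprintf(strings[["category_blurb"]], c$name), "",
           sprintf("{{#default_form:%s}}", cname))
  filters <- character()
  for (p in c$properties) {
    if (!drilldown_filterable(p)) next
    f <- sprintf("%s (property=%s", p$label, p$page_name)
    if (nzchar(p$group)) f <- sprintf("%s, group=%s", f, p$group)
    filters <- c(filters, paste0(f, ")"))
  }
  if (length(filters))
    out <- c(out, sprintf("{{#drilldowninfo:filters=%s}}",
                          paste(filters, collapse = ",")))
  if (!is.na(c$parent))
    out <- c(out, sprintf("[[Category:%s]]", c$parent))
  new_wiki_page(cname, WIKI_NAMESPACES[["CATEGORY"]],
                paste(out, collapse = "\n"))
}

# --- main page and whole site -----------------------------------------------

emit_main_page <- function(schema, strings = ui_strings()) {
  cats <- category_names(schema)
  out <- c(sprintf(strings[["welcome"]], schema$site_title), "",
           strings[["intro"]], "",
           sprintf("== %s ==", strings[["sec_database"]]),
           sprintf("* [[Special:FormEdit/%s|%s]] ([[:Category:%s|%s]])",
                   property_page_name(cats),
                   sprintf(strings[["add_entry"]], cats),
                   property_page_name(cats), strings[["browse"]]),
           "",
           sprintf("== %s ==", strings[["sec_query"]]),
           sprintf("* [[Special:BrowseData/%s|%s]]",
                   property_page_name(cats),
                   sprintf(strings[["drilldown"]], cats)),
           sprintf("* [[Special:Ask|%s]]", strings[["ask_query"]]),
           "",
           sprintf("== %s ==", strings[["sec_export"]]),
           sprintf("* [[Special:Export|%s]]", strings[["export_pages"]]))
  new_wiki_page("Main Page", WIKI_NAMESPACES[["MAIN"]],
                paste(out, collapse = "\n"))
}

# Every property page the site needs, deduplicated by page name, in schema
# order: per category its connection property then its own properties, then
# the aspect relations in first-use order.
site_property_specs <- function(schema) {
  specs <- list()
  seen <- character()
  add <- function(p) {
    if (!(p$page_name %in% seen)) {
      seen <<- c(seen, p$page_name)
      specs[[length(specs) + 1L]] <<- p
    }
  }
  for (c in schema$categories) {
    if (!is.null(c$connection)) add(connection_property_spec(c$connection))
    for (p in c$properties) add(p)
  }
  for (c in schema$categories)
    for (p in c$properties)
      for (rel in names(p$aspects)) add(aspect_relation_spec(rel))
  specs
}

#' Compile a schema into a full site definition
#'
#' Produces, in deterministic order: the main page, then per category its
#' template, form and category page, then one property page for every
#' distinct property (a category's own properties, the connection properties
#' realizing one-to-many links, and the aspect relations used by complex
#' properties). The result satisfies property-page closure: every property
#' annotated anywhere in the emitted wikitext has a Property page in the
#' document.
#'
#' @param schema A valid `smw_schema`; invalid schemas are refused.
#' @param lang UI language for the boilerplate text (defaults to the
#'   schema's).
#' @param main_text Optional replacement wikitext for the main page.
#' @param timestamp Fixed revision timestamp written to the XML (ISO-8601,
#'   UTC); fixed by default so output is byte-reproducible.
#' @return An `smw_wiki_doc`.
#' @export
emit_site <- function(schema, lang = schema$language, main_text = NULL,
                      timestamp = "2020-01-01T00:00:00Z") {
  stop_if_invalid(schema)
  strings <- ui_strings(lang)
  pages <- list()
  main <- emit_main_page(schema, strings)
  if (!is.null(main_text)) main$text <- main_text
  pages[[1L]] <- main
  for (c in schema$categories) {
    pages <- c(pages, list(emit_template(c, strings),
                           emit_form(c, strings),
                           emit_category_page(c, strings)))
  }
  for (p in site_property_specs(schema))
    pages <- c(pages, list(emit_property_page(p, strings)))
  new_wiki_doc(pages, sitename = schema$site_title, lang = lang,
               timestamp = timestamp)
}

#' Expected number of pages for a compiled site
#'
#' `1 + 3 * |categories| + |distinct properties, connections and aspect
#' relations|` — the main page, three pages per category, and one page per
#' distinct property.
#'
#' @param schema A valid `smw_schema`.
#' @return An integer.
#' @export
expected_page_count <- function(schema) {
  1L + 3L * length(schema$categories) + length(site_property_specs(schema))
}

# SMW builtin properties that have no generated page.
BUILTIN_PROPERTIES <- c("Has type", "Allows value")

#' Check property-page closure of a site document
#'
#' Scans every page's wikitext for `[[Name::...]]` annotations and reports
#' the (non-builtin) property names that lack a Property-namespace page.
#'
#' @param doc An `smw_wiki_doc`.
#' @return Character vector of dangling property names (empty when closure
#'   holds).
#' @export
check_property_closure <- function(doc) {
  have <- vapply(Filter(function(p) p$ns == WIKI_NAMESPACES[["PROPERTY"]],
                        doc$pages),
                 `[[`, character(1), "title")
  referenced <- character()
  for (p in doc$pages) {
    m <- regmatches(p$text,
                    gregexpr("\\[\\[([^][|]+?)::", p$text))[[1]]
    if (length(m))
      referenced <- c(referenced, sub("::$", "", sub("^\\[\\[", "", m)))
  }
  referenced <- unique(trimws(referenced))
  referenced <- setdiff(referenced, BUILTIN_PROPERTIES)
  # the wiki resolves titles first-letter case-insensitively
  referenced <- paste0(toupper(substring(referenced, 1, 1)),
                       substring(referenced, 2))
  sort_c(setdiff(unique(referenced), have))
}
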