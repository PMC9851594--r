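MEDIAWIKI_EXPORT_NS <- "http://www.mediawiki.org/xml/export-0.10/"

#' Serialize a site document to MediaWiki import XML
#'
#' Writes the standard page-dump dialect (root `mediawiki` element in the
#' export-0.10 namespace) that a wiki's Special:Import facility consumes:
#' a `siteinfo` header naming the site, generator and the namespaces used,
#' then one `page` element per wiki page carrying its full title, namespace
#' key and a single revision with model `wikitext`, format `text/x-wiki` and
#' a fixed timestamp and contributor so that equal inputs serialize to equal
#' bytes.
#'
#' @param doc An `smw_wiki_doc`.
#' @return A single UTF-8 XML string.
#' @export
serialize_xml <- function(doc) {
  root <- xml2::xml_new_root(
    "mediawiki",
    xmlns = MEDIAWIKI_EXPORT_NS,
    "xmlns:xsi" = "http://www.w3.org/2001/XMLSchema-instance",
    "xsi:schemaLocation" = paste(MEDIAWIKI_EXPORT_NS,
                                 "http://www.mediawiki.org/xml/export-0.10.xsd"),
    version = "0.10",
    "xml:lang" = doc$lang)

  si <- xml2::xml_add_child(root, "siteinfo")
  xml2::xml_add_child(si, "sitename", doc$sitename)
  xml2::xml_add_child(si, "generator", doc$generator)
  xml2::xml_add_child(si, "case", "first-letter")
  nss <- xml2::xml_add_child(si, "namespaces")
  for (i in seq_along(WIKI_NAMESPACES)) {
    key <- WIKI_NAMESPACES[[i]]
    nm <- NS_PREFIXES[[as.character(key)]]
    node <- xml2::xml_add_child(nss, "namespace", nm)
    xml2::xml_set_attr(node, "key", as.character(key))
    xml2::xml_set_attr(node, "case", "first-letter")
  }

  for (i in seq_along(doc$pages)) {
    p <- doc$pages[[i]]
    pg <- xml2::xml_add_child(root, "page")
    xml2::xml_add_child(pg, "title", full_title(p))
    xml2::xml_add_child(pg, "ns", as.character(p$ns))
    xml2::xml_add_child(pg, "id", as.character(i))
    rev <- xml2::xml_add_child(pg, "revision")
    xml2::xml_add_child(rev, "id", as.character(i))
    xml2::xml_add_child(rev, "timestamp", doc$timestamp)
    ctb <- xml2::xml_add_child(rev, "contributor")
    xml2::xml_add_child(ctb, "username", "Maintenance script")
    xml2::xml_add_child(ctb, "id", "0")
    xml2::xml_add_child(rev, "model", "wikitext")
    xml2::xml_add_child(rev, "format", "text/x-wiki")
    txt <- xml2::xml_add_child(rev, "text", p$text)
    xml2::xml_set_attr(txt, "xml:space", "preserve")
  }

  as.character(root, options = character())
}

#' Write a site document to an XML file
#' @param doc An `smw_wiki_doc`.
#' @param path Output path (`"-"` streams to standard output).
#' @return Invisibly, the XML string.
#' @export
write_site_xml <- function(doc, path) {
  xml <- serialize_xml(doc)
  if (identical(path, "-")) cat(xml)
  else writeLines(xml, path, sep = "", useBytes = TRUE)
  invisible(xml)
}

# x must be a subsequence of `allowed` (each in order, repeats via `repeats`).
check_child_order <- function(found, allowed, repeats = character()) {
  pos <- 0L
  for (nm in found) {
    at <- match(nm, allowed)
    if (is.na(at)) return(sprintf("unexpected element <%s>", nm))
    if (at < pos) return(sprintf("element <%s> out of order", nm))
    if (at == pos && !(nm %in% repeats))
      return(sprintf("element <%s> repeated", nm))
    pos <- at
  }
  NULL
}

#' Structurally validate MediaWiki import XML (export-0.10 dialect)
#'
#' Checks well-formedness and the structural rules of the export-0.10
#' page-dump dialect: root `mediawiki` element in the export-0.10 namespace
#' with `version="0.10"`; an optional leading `siteinfo` with its children in
#' canonical order; each `page` holding `title`, `ns`, optional `id` and at
#' least one `revision` in order; revisions with ISO timestamps, model
#' `wikitext`, format `text/x-wiki` and a `text` element; and
#' namespace-unique titles.
#'
#' @param xml A single XML string or a path to an XML file.
#' @return Character vector of problems; `character(0)` means the document
#'   conforms.
#' @export
check_mediawiki_xml <- function(xml) {
  doc <- tryCatch(xml2::read_xml(xml), error = function(e)
    conditionMessage(e))
  if (is.character(doc)) return(sprintf("not well-formed XML: %s", doc))
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)

  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "mediawiki") note("root element is not <mediawiki>")
  nsuri <- xml2::xml_ns(doc)
  if (!MEDIAWIKI_EXPORT_NS %in% as.character(nsuri))
    note("document is not in the MediaWiki export-0.10 namespace")
  if (!identical(xml2::xml_attr(root, "version"), "0.10"))
    note("missing or wrong version attribute (expected 0.10)")

  kids <- xml2::xml_children(root)
  kid_names <- xml2::xml_name(kids)
  bad <- check_child_order(kid_names, c("siteinfo", "page"), repeats = "page")
  if (!is.null(bad)) note(paste0("under <mediawiki>: ", bad))

  si <- kids[kid_names == "siteinfo"]
  if (length(si) == 1L) {
    bad <- check_child_order(
      xml2::xml_name(xml2::xml_children(si[[1]])),
      c("sitename", "dbname", "base", "generator", "case", "namespaces"))
    if (!is.null(bad)) note(paste0("under <siteinfo>: ", bad))
  }

  titles <- character()
  for (pg in kids[kid_names == "page"]) {
    pk <- xml2::xml_children(pg)
    pn <- xml2::xml_name(pk)
    bad <- check_child_order(pn,
                             c("title", "ns", "id", "redirect", "restrictions",
                               "revision"),
                             repeats = "revision")
    if (!is.null(bad)) note(paste0("under <page>: ", bad))
    title <- xml2::xml_text(pk[pn == "title"])
    if (length(title) != 1L || !nzchar(title)) note("page without a title")
    nsv <- xml2::xml_text(pk[pn == "ns"])
    if (length(nsv) != 1L || is.na(suppressWarnings(as.integer(nsv))))
      note(sprintf("page '%s': missing or non-integer <ns>",
                   paste(title, collapse = "")))
    if (!any(pn == "revision"))
      note(sprintf("page '%s': no revision", title))
    titles <- c(titles, paste0(nsv, ":", title))
    for (rev in pk[pn == "revision"]) {
      rk <- xml2::xml_children(rev)
      rn <- xml2::xml_name(rk)
      bad <- check_child_order(rn,
                               c("id", "parentid", "timestamp", "contributor",
                                 "minor", "comment", "origin", "model",
                                 "format", "text", "sha1"))
      if (!is.null(bad)) note(sprintf("page '%s' revision: %s", title, bad))
      ts <- xml2::xml_text(rk[rn == "timestamp"])
      if (length(ts) != 1L ||
          !grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}T[0-9]{2}:[0-9]{2}:[0-9]{2}Z$", ts))
        note(sprintf("page '%s': missing or malformed <timestamp>", title))
      if (!identical(xml2::xml_text(rk[rn == "model"]), "wikitext"))
        note(sprintf("page '%s': revision model is not wikitext", title))
      if (!identical(xml2::xml_text(rk[rn == "format"]), "text/x-wiki"))
        note(sprintf("page '%s': revision format is not text/x-wiki", title))
      if (!any(rn == "text"))
        note(sprintf("page '%s': revision without <text>", title))
    }
  }
  if (anyDuplicated(titles))
    note(sprintf("duplicate page titles: %s",
                 paste(unique(titles[duplicated(titles)]), collapse = ", ")))
  problems
}
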