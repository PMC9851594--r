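#' Normalize a property label into a Prolog atom
#'
#' Lowercases, collapses every run of non-alphanumeric characters to a single
#' underscore, trims leading/trailing underscores and prefixes `p_` when the
#' result would start with a digit; the result is a bare lowercase atom.
#' Idempotent.
#'
#' @param label Character vector of property labels.
#' @return Character vector of predicate atoms.
#' @examples
#' normalize_predicate("Has temperature")  # "has_temperature"
#' normalize_predicate("2nd visit date")   # "p_2nd_visit_date"
#' @export
normalize_predicate <- function(label) {
  vapply(label, function(s) {
    if (!nzchar(s)) stop("empty label cannot become a predicate")
    a <- tolower(s)
    a <- gsub("[^a-z0-9]+", "_", a)
    a <- gsub("^_+|_+$", "", a)
    if (!nzchar(a)) stop(sprintf("label %s reduces to an empty atom",
                                 deparse(s)))
    if (grepl("^[0-9]", a)) a <- paste0("p_", a)
    a
  }, character(1), USE.NAMES = FALSE)
}

# All predicates a schema gives rise to; errors on collisions since two
# labels mapping to one atom would silently merge their facts.
schema_predicates <- function(schema) {
  labs <- character()
  for (c in schema$categories) {
    if (!is.null(c$connection)) labs <- c(labs, c$connection$property)
    labs <- c(labs, vapply(c$properties, `[[`, character(1), "label"))
  }
  labs <- unique(labs)
  preds <- normalize_predicate(labs)
  if (anyDuplicated(preds)) {
    dup <- preds[duplicated(preds)]
    clash <- labs[preds %in% dup]
    stop("labels normalize to colliding predicates: ",
         paste(clash, collapse = ", "))
  }
  stats::setNames(preds, labs)
}

quote_atom <- function(s) {
  paste0("'", gsub("'", "''", s, fixed = TRUE), "'")
}

prolog_object <- function(v, p) {
  switch(p$type,
    NUMBER = num_chr(v),
    DATE = {
      lt <- as.POSIXlt(v)
      sprintf("date(%d,%d,%d)", lt$year + 1900L, lt$mon + 1L, lt$mday)
    },
    COORDINATES = quote_atom(paste0(num_chr(v[1]), ", ", num_chr(v[2]))),
    quote_atom(as.character(v))
  )
}

#' Export a record set as ternary Prolog facts
#'
#' Writes one ground term per non-MISSING cell,
#' `fact('<Subject>', <predicate>, <Object>).`, reifying the property as the
#' second argument so triples keep a fixed arity, plus one
#' `fact('<Child>', <connection_predicate>, '<Parent>').` per parent link.
#' Numbers are bare, dates become `date(Y,M,D)` compound terms, everything
#' else is a single-quoted atom with internal quotes doubled. Records are
#' ordered by title (byte order) and cells by schema property order, so the
#' export is deterministic. With `per_property = TRUE` each property becomes
#' its own unary-subject predicate, e.g.
#' `has_temperature('Patients 1', 38.5).`
#'
#' @param rs An `smw_recordset` with titles assigned.
#' @param per_property Emit `<predicate>(Subject, Object).` instead of
#'   `fact/3`.
#' @return A single string (UTF-8, LF line endings) loadable by a standard
#'   Prolog interpreter.
#' @export
export_facts <- function(rs, per_property = FALSE) {
  schema <- rs$schema
  preds <- schema_predicates(schema)
  header <- c(sprintf("%% facts exported from schema '%s'", schema$site_title),
              sprintf("%% generation seed: %s",
                      if (is.na(rs$seed)) "none" else rs$seed))
  lines <- character()
  emit <- function(subject, pred, object) {
    if (per_property)
      sprintf("%s(%s, %s).", pred, quote_atom(subject), object)
    else
      sprintf("fact(%s, %s, %s).", quote_atom(subject), pred, object)
  }
  titles <- vapply(rs$records, `[[`, character(1), "title")
  for (r in rs$records[order_c(titles)]) {
    cat_ <- get_category(schema, r$category)
    for (p in cat_$properties) {
      v <- r$values[[p$label]]
      if (is.null(v)) next
      lines <- c(lines, emit(r$title, preds[[p$label]], prolog_object(v, p)))
    }
    if (!is.null(cat_$connection) && !is.na(r$parent_title))
      lines <- c(lines, emit(r$title, preds[[cat_$connection$property]],
                             quote_atom(r$parent_title)))
  }
  paste0(paste(c(header, lines), collapse = "\n"), "\n")
}

#' Export the aspect decomposition of complex properties
#'
#' Complex clinical properties can be decomposed into (relation, value)
#' aspect pairs; each pair becomes a ground term
#' `property_aspect(<predicate>, <relation>, '<value>').` so an external
#' reasoner can select, e.g., every measurement taken on the left ear
#' regardless of the exact property.
#'
#' @param schema A valid `smw_schema`.
#' @return A single string of Prolog facts (header comments only when no
#'   property declares aspects).
#' @export
export_aspect_facts <- function(schema) {
  stop_if_invalid(schema)
  preds <- schema_predicates(schema)
  lines <- sprintf("%% property aspects for schema '%s'", schema$site_title)
  for (c in schema$categories)
    for (p in c$properties)
      for (rel in names(p$aspects))
        lines <- c(lines,
                   sprintf("property_aspect(%s, %s, %s).",
                           preds[[p$label]], normalize_predicate(rel),
                           quote_atom(p$aspects[[rel]])))
  paste0(paste(lines, collapse = "\n"), "\n")
}
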