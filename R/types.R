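#' Property types understood by the schema dialect
#'
#' Each tag maps to exactly one Semantic MediaWiki datatype. `TRISTATE` and
#' `ENUM` are stored as SMW `Text` restricted by an allowed-value domain;
#' `TRISTATE` always carries the canonical three-valued domain
#' `Yes`/`No`/`NA`, where `NA` records "not available" explicitly, as opposed
#' to a cell that was never filled in.
#'
#' @format A named character vector mapping type tags to SMW datatype names.
#' @export
SMW_TYPES <- c(
  TEXT        = "Text",
  NUMBER      = "Number",
  DATE        = "Date",
  BOOLEAN     = "Boolean",
  TRISTATE    = "Text",
  ENUM        = "Text",
  PAGE        = "Page",
  COORDINATES = "Geographic coordinate",
  URL         = "URL"
)

#' Canonical three-valued domain for TRISTATE properties
#' @export
TRISTATE_DOMAIN <- c("Yes", "No", "NA")

#' Default vocabulary of aspect relations
#'
#' Complex clinical properties ("Pure tone average of vocal gain during last
#' control exam with intracochlear device on left ear") can be decomposed into
#' (relation, value) aspect pairs attached to the property; the relations are
#' drawn from this configurable vocabulary.
#' @export
ASPECT_VOCABULARY <- c("measure", "exam", "device", "laterality", "organ",
                       "time")

# Characters MediaWiki forbids in page titles.
FORBIDDEN_TITLE_CHARS <- c("#", "<", ">", "[", "]", "|", "{", "}")

#' Normalize a property label into a valid wiki page title
#'
#' Trims and collapses whitespace, strips characters MediaWiki forbids in
#' titles (`# < > [ ] | { }`) and capitalizes the first letter, as MediaWiki
#' itself does. The function is idempotent.
#'
#' @param label A character vector of human-readable labels.
#' @return A character vector of valid page titles.
#' @examples
#' property_page_name("has  temperature ")  # "Has temperature"
#' property_page_name("BMI [kg/m2]")        # "BMI kg/m2"
#' @export
property_page_name <- function(label) {
  stopifnot(is.character(label))
  out <- vapply(label, function(s) {
    if (is.na(s) || !nzchar(s)) stop("empty label cannot become a page title")
    s <- gsub("[][#<>|{}]", "", s)
    s <- gsub("[[:space:]]+", " ", trimws(s))
    if (!nzchar(s)) stop(sprintf("label %s reduces to an empty title",
                                 deparse(s)))
    paste0(toupper(substring(s, 1, 1)), substring(s, 2))
  }, character(1), USE.NAMES = FALSE)
  out
}

is_valid_title <- function(s) {
  nzchar(s) &
    !grepl("[][#<>|{}]", s) &
    substring(s, 1, 1) == toupper(substring(s, 1, 1)) &
    !grepl("^[[:space:]]|[[:space:]]$|[[:space:]]{2}", s)
}

# --- constructors -----------------------------------------------------------

new_constraint <- function(kind = "NONE", min = NA_real_, max = NA_real_,
                           values = character(), target = NA_character_) {
  structure(list(kind = kind, min = min, max = max, values = values,
                 target = target),
            class = "smw_constraint")
}

new_property <- function(label, type, constraint = new_constraint(),
                         unit = "", note = "", aspects = character(),
                         group = "", category = NA_character_,
                         line = NA_integer_) {
  structure(list(
    label = label,
    page_name = property_page_name(label),
    category = category,
    group = group,
    type = type,
    constraint = constraint,
    unit = unit,
    note = note,
    aspects = aspects,  # named character vector: c(relation = value, ...)
    line = line
  ), class = "smw_property")
}

new_category <- function(name, parent = NA_character_, connection = NULL,
                         line = NA_integer_) {
  structure(list(
    name = name,
    parent = parent,
    connection = connection,  # list(property =, target =) or NULL
    groups = character(),
    properties = list(),
    line = line
  ), class = "smw_category_spec")
}

new_schema <- function(categories = list(), site_title = "Wiki database",
                       language = "en",
                       aspect_vocab = ASPECT_VOCABULARY) {
  structure(list(
    categories = categories,
    site_title = site_title,
    language = language,
    aspect_vocab = aspect_vocab
  ), class = "smw_schema")
}

category_names <- function(schema) {
  vapply(schema$categories, `[[`, character(1), "name")
}

get_category <- function(schema, name) {
  for (c in schema$categories) if (c$name == name) return(c)
  NULL
}

get_property <- function(category, label) {
  for (p in category$properties) if (p$label == label) return(p)
  NULL
}

# All (category, property) pairs as a flat list, schema order.
schema_properties <- function(schema) {
  unlist(lapply(schema$categories, `[[`, "properties"), recursive = FALSE)
}

#' @export
print.smw_schema <- function(x, ...) {
  cat(sprintf("<smw_schema> \"%s\" (lang %s): %d categories\n",
              x$site_title, x$language, length(x$categories)))
  for (c in x$categories) {
    conn <- if (!is.null(c$connection))
      sprintf(" --[%s]--> %s", c$connection$property, c$connection$target)
    else ""
    par <- if (!is.na(c$parent)) sprintf(" (subclass of %s)", c$parent) else ""
    cat(sprintf("  %s%s%s: %d properties\n", c$name, par, conn,
                length(c$properties)))
  }
  invisible(x)
}
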