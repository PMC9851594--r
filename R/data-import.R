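MISSING <- structure(NA, class = "smw_missing")

new_record <- function(category, values = list(), index = NA_integer_,
                       title = NA_character_, parent_index = NA_integer_,
                       parent_title = NA_character_) {
  structure(list(category = category, index = index, title = title,
                 parent_index = parent_index, parent_title = parent_title,
                 values = values),  # named list, non-missing cells only
            class = "smw_record")
}

new_recordset <- function(schema, records = list(), seed = NA_integer_) {
  structure(list(schema = schema, records = records, seed = seed),
            class = "smw_recordset")
}

#' @export
print.smw_recordset <- function(x, ...) {
  cats <- vapply(x$records, `[[`, character(1), "category")
  cat(sprintf("<smw_recordset> %d records (%s)\n", length(x$records),
              paste(sprintf("%s: %d", names(table(cats)), table(cats)),
                    collapse = ", ")))
  invisible(x)
}

#' Merge record sets bound to the same schema
#' @param ... `smw_recordset` objects sharing one schema.
#' @return A single `smw_recordset`.
#' @export
combine_records <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1L)
  new_recordset(sets[[1]]$schema,
                unlist(lapply(sets, `[[`, "records"), recursive = FALSE),
                seed = sets[[1]]$seed)
}

# --- value encoding ---------------------------------------------------------

WIKITEXT_ESCAPES <- c("|" = "&#124;", "{" = "&#123;", "}" = "&#125;",
                      "=" = "&#61;")

escape_wikitext <- function(s) {
  for (ch in names(WIKITEXT_ESCAPES))
    s <- gsub(ch, WIKITEXT_ESCAPES[[ch]], s, fixed = TRUE)
  s
}

unescape_wikitext <- function(s) {
  for (ch in names(WIKITEXT_ESCAPES))
    s <- gsub(WIKITEXT_ESCAPES[[ch]], ch, s, fixed = TRUE)
  s
}

#' Encode a typed value as wikitext-safe template-argument text
#'
#' Numbers render with no locale separators and no scientific notation,
#' dates as ISO-8601, coordinates as `"lat, lon"` decimal degrees; the
#' wikitext-active characters `|`, `{`, `}` and `=` in strings are replaced
#' by their numeric character entities. [decode_value()] inverts the
#' encoding.
#'
#' @param v A typed value satisfying `p`'s constraint.
#' @param p The `smw_property` the value belongs to.
#' @return A single string.
#' @export
encode_value <- function(v, p) {
  switch(p$type,
    NUMBER = num_chr(v),
    DATE = format(v, "%Y-%m-%d"),
    COORDINATES = paste0(num_chr(v[1]), ", ", num_chr(v[2])),
    escape_wikitext(as.character(v))
  )
}

#' Decode template-argument text back into a typed value
#' @param s A string produced by [encode_value()].
#' @param p The `smw_property` the value belongs to.
#' @return The typed value.
#' @export
decode_value <- function(s, p) {
  switch(p$type,
    NUMBER = as.numeric(s),
    DATE = as.Date(s, format = "%Y-%m-%d"),
    COORDINATES = as.numeric(trimws(strsplit(s, ",", fixed = TRUE)[[1]])),
    unescape_wikitext(s)
  )
}

# Plain TSV cell rendering (no wikitext escaping; tabs/newlines are
# structural in the dialect and must not occur inside values).
tsv_cell <- function(v, p) {
  s <- switch(p$type,
    NUMBER = num_chr(v),
    DATE = format(v, "%Y-%m-%d"),
    COORDINATES = paste0(num_chr(v[1]), ", ", num_chr(v[2])),
    as.character(v)
  )
  if (grepl("[\t\n\r]", s))
    stop(sprintf("value of '%s' contains a structural character", p$label))
  s
}

# --- cell parsing -----------------------------------------------------------

cell_error <- function(msg) structure(list(msg = msg), class = "cell_error")

# Returns the typed value, or a `cell_error` carrying the message.
parse_cell <- function(raw, p) {
  switch(p$type,
    NUMBER = {
      v <- suppressWarnings(as.numeric(raw))
      if (is.na(v)) cell_error(sprintf("'%s' is not a number", raw)) else v
    },
    DATE = {
      v <- parse_iso_date(raw)
      if (is.na(v)) cell_error(sprintf("'%s' is not an ISO-8601 date", raw))
      else v
    },
    BOOLEAN = {
      if (raw %in% c("Yes", "No")) raw
      else cell_error(sprintf("'%s' is not Yes/No", raw))
    },
    TRISTATE = {
      if (raw %in% TRISTATE_DOMAIN) raw
      else cell_error(sprintf("'%s' is not Yes/No/NA", raw))
    },
    COORDINATES = {
      parts <- suppressWarnings(
        as.numeric(trimws(strsplit(raw, ",", fixed = TRUE)[[1]])))
      if (length(parts) != 2L || anyNA(parts))
        cell_error(sprintf("'%s' is not 'lat, lon'", raw))
      else parts
    },
    PAGE = {
      if (is_valid_title(raw)) raw
      else cell_error(sprintf("'%s' is not a valid page title", raw))
    },
    raw  # TEXT, URL, ENUM (domain checked as a constraint)
  )
}

# TRUE, or a character message describing the constraint violation.
check_value <- function(v, p) {
  cons <- p$constraint
  switch(cons$kind,
    RANGE = {
      x <- if (p$type == "DATE") as.numeric(v) else v
      if (x < cons$min || x > cons$max)
        sprintf("value %s outside range %s", tsv_cell(v, p),
                serialize_constraint(cons, p$type))
      else TRUE
    },
    DOMAIN = if (!v %in% cons$values)
      sprintf("value '%s' not in domain %s", v,
              paste(cons$values, collapse = "|"))
    else TRUE,
    TRUE
  )
}

#' Parse a data TSV against a schema category
#'
#' The header row names the category's property labels (any order, any
#' subset); the reserved header `!parent` holds, for categories with a
#' one-to-many connection, the 1-based row index of the parent entity in its
#' own data file. Empty cells become MISSING; the literal cell `NA` in a
#' three-valued column is the explicit "not available" value, *not* MISSING.
#' Unknown column labels, unparseable cells and constraint violations are
#' reported as row-addressed `ERROR` diagnostics retrievable with
#' [schema_diagnostics()].
#'
#' @param text The data TSV as a single string or character vector of lines.
#' @param schema A valid `smw_schema`.
#' @param category Name of the category the rows instantiate.
#' @return An `smw_recordset` (titles unassigned; see [assign_titles()]).
#' @export
parse_data <- function(text, schema, category) {
  stop_if_invalid(schema)
  cat_ <- get_category(schema, category)
  if (is.null(cat_)) stop(sprintf("unknown category '%s'", category))
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\r?\n")[[1]]
  # an interior blank line is a row of all-MISSING cells; only trailing
  # blank lines are ignored
  while (length(text) && !nzchar(text[length(text)]))
    text <- text[-length(text)]
  diags <- diag_new()
  if (length(text) == 0L) {
    rs <- new_recordset(schema)
    attr(rs, "diagnostics") <- diag_add(diags, "ERROR", 1L, "missing header row")
    return(rs)
  }
  text[1] <- sub("^﻿", "", text[1])
  header <- trimws(strsplit(text[1], "\t", fixed = TRUE)[[1]])
  labels <- vapply(cat_$properties, `[[`, character(1), "label")
  for (h in setdiff(header, c(labels, "!parent")))
    diags <- diag_add(diags, "ERROR", 1L,
                      sprintf("unknown column label '%s' for category '%s'",
                              h, category))
  records <- list()
  for (i in seq_along(text)[-1]) {
    cells <- strsplit(text[i], "\t", fixed = TRUE)[[1]]
    cells <- c(cells, rep("", max(0L, length(header) - length(cells))))
    values <- list()
    parent_index <- NA_integer_
    for (j in seq_along(header)) {
      raw <- trimws(cells[j])
      if (!nzchar(raw)) next  # MISSING
      h <- header[j]
      if (h == "!parent") {
        k <- suppressWarnings(as.integer(raw))
        if (is.na(k) || k < 1L)
          diags <- diag_add(diags, "ERROR", i,
                            sprintf("row %d: '!parent' must be a positive row index, got '%s'",
                                    i - 1L, raw))
        else parent_index <- k
        next
      }
      p <- get_property(cat_, h)
      if (is.null(p)) next  # already reported at header
      v <- parse_cell(raw, p)
      if (inherits(v, "cell_error")) {
        diags <- diag_add(diags, "ERROR", i,
                          sprintf("row %d, column '%s': %s", i - 1L, h, v$msg))
        next
      }
      ok <- check_value(v, p)
      if (is.character(ok)) {
        diags <- diag_add(diags, "ERROR", i,
                          sprintf("row %d, column '%s': %s", i - 1L, h, ok))
        next
      }
      values[[h]] <- v
    }
    records[[length(records) + 1L]] <-
      new_record(category, values, parent_index = parent_index)
  }
  rs <- new_recordset(schema, records)
  attr(rs, "diagnostics") <- diags
  rs
}

#' Assign progressive-number titles to records
#'
#' Entities are deliberately named with progressive numbers rather than
#' personal details: records of root categories get titles
#' `"<Category> <index>"` with consecutive indices starting at
#' `start_index`; records of a category with a one-to-many connection become
#' subpages of their parent, `"<parent title>/<Category> <k>"` with `k`
#' counted per parent from 1. Because the wiki's own uniqueness constraint
#' merely signals conflicts, collisions (including with `existing_titles`
#' from an earlier import) are a hard error here.
#'
#' @param rs An `smw_recordset` (possibly combining several categories).
#' @param start_index First index for root-category records (>= 1); raise it
#'   for incremental imports into a populated site.
#' @param existing_titles Titles already present in the target wiki.
#' @return The record set with `index`, `title` and `parent_title` filled in.
#' @export
assign_titles <- function(rs, start_index = 1L, existing_titles = character()) {
  stopifnot(start_index >= 1L)
  schema <- rs$schema
  cats <- category_names(schema)
  conn_target <- vapply(schema$categories, function(c)
    if (is.null(c$connection)) NA_character_ else c$connection$target,
    character(1))
  names(conn_target) <- cats

  # topological order over the connection links (parents before children)
  order <- character()
  remaining <- cats
  while (length(remaining)) {
    ready <- remaining[is.na(conn_target[remaining]) |
                         !(conn_target[remaining] %in% remaining)]
    if (!length(ready)) stop("connection links form a cycle")
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }

  rec_cat <- vapply(rs$records, `[[`, character(1), "category")
  titles_by_cat <- list()
  for (cname in order) {
    idx <- which(rec_cat == cname)
    if (!length(idx)) next
    target <- conn_target[[cname]]
    if (is.na(target)) {
      for (k in seq_along(idx)) {
        i <- idx[k]
        rs$records[[i]]$index <- start_index + k - 1L
        rs$records[[i]]$title <- sprintf("%s %d", cname, start_index + k - 1L)
      }
    } else {
      parent_titles <- titles_by_cat[[target]]
      counter <- integer()
      for (i in idx) {
        pi <- rs$records[[i]]$parent_index
        if (is.na(pi) || is.null(parent_titles) || pi > length(parent_titles))
          stop(sprintf(
            "record of '%s' has no resolvable parent (index %s in '%s')",
            cname, pi, target))
        pt <- parent_titles[pi]
        key <- as.character(pi)
        counter[key] <- (if (is.na(counter[key])) 0L else counter[key]) + 1L
        rs$records[[i]]$index <- counter[[key]]
        rs$records[[i]]$parent_title <- pt
        rs$records[[i]]$title <- sprintf("%s/%s %d", pt, cname, counter[[key]])
      }
    }
    titles_by_cat[[cname]] <-
      vapply(rs$records[idx], `[[`, character(1), "title")
  }
  all_titles <- vapply(rs$records, `[[`, character(1), "title")
  clash <- c(all_titles[duplicated(all_titles)],
             intersect(all_titles, existing_titles))
  if (length(clash))
    stop("title collision: ", paste(unique(clash), collapse = ", "))
  rs
}

#' Emit importable wiki pages for a record set
#'
#' One main-namespace page per record, whose wikitext is a single call to the
#' category's template: one named argument per non-MISSING value (encoded
#' with [encode_value()]) in schema property order, preceded by the
#' connection argument pointing at the parent entity.
#'
#' @param rs An `smw_recordset` with titles assigned.
#' @param timestamp Fixed revision timestamp (see [emit_site()]).
#' @return An `smw_wiki_doc`.
#' @export
emit_data_xml <- function(rs, timestamp = "2020-01-01T00:00:00Z") {
  schema <- rs$schema
  pages <- lapply(rs$records, function(r) {
    cat_ <- get_category(schema, r$category)
    args <- character()
    if (!is.null(cat_$connection) && !is.na(r$parent_title))
      args <- sprintf("%s=%s", property_page_name(cat_$connection$property),
                      r$parent_title)
    for (p in cat_$properties) {
      if (is.null(r$values[[p$label]])) next
      args <- c(args, sprintf("%s=%s", p$page_name,
                              encode_value(r$values[[p$label]], p)))
    }
    text <- sprintf("{{%s%s}}", property_page_name(r$category),
                    if (length(args)) paste0("|", paste(args, collapse = "|"))
                    else "")
    new_wiki_page(r$title, WIKI_NAMESPACES[["MAIN"]], text)
  })
  new_wiki_doc(pages, sitename = schema$site_title, lang = schema$language,
               timestamp = timestamp)
}

#' Extract the template call of a data page
#'
#' Inverse of [emit_data_xml()] for a single page: returns the template name
#' and its named arguments (still encoded; pair with [decode_value()]).
#'
#' @param text Wikitext consisting of one `{{Name|a=b|...}}` call.
#' @return A list with elements `template` and `args` (named character).
#' @export
parse_template_call <- function(text) {
  m <- regmatches(text, regexec("^\\{\\{([^|}]+)(.*)\\}\\}$", text))[[1]]
  if (length(m) != 3L) stop("not a single template call: ", text)
  rest <- m[3]
  args <- character()
  if (nzchar(rest)) {
    parts <- strsplit(sub("^\\|", "", rest), "|", fixed = TRUE)[[1]]
    for (pt in parts) {
      kv <- regmatches(pt, regexec("^([^=]+)=(.*)$", pt))[[1]]
      if (length(kv) != 3L) stop("malformed template argument: ", pt)
      args[[kv[2]]] <- kv[3]
    }
  }
  list(template = m[2], args = args)
}

#' Serialize one category of a record set to data TSV
#'
#' The inverse of [parse_data()]: writes the category's property labels as
#' the header (preceded by `!parent` for connected categories) and one row
#' per record, empty cells for MISSING values.
#'
#' @param rs An `smw_recordset`.
#' @param category Category name to serialize.
#' @return A single TSV string, LF line endings.
#' @export
records_to_tsv <- function(rs, category) {
  cat_ <- get_category(rs$schema, category)
  if (is.null(cat_)) stop(sprintf("unknown category '%s'", category))
  labels <- vapply(cat_$properties, `[[`, character(1), "label")
  header <- c(if (!is.null(cat_$connection)) "!parent", labels)
  rows <- vapply(Filter(function(r) r$category == category, rs$records),
                 function(r) {
    cells <- character()
    if (!is.null(cat_$connection))
      cells <- if (is.na(r$parent_index)) "" else as.character(r$parent_index)
    for (p in cat_$properties) {
      v <- r$values[[p$label]]
      cells <- c(cells, if (is.null(v)) "" else tsv_cell(v, p))
    }
    paste(cells, collapse = "\t")
  }, character(1))
  paste0(paste(c(paste(header, collapse = "\t"), rows), collapse = "\n"), "\n")
}

#' Read and parse a data TSV file
#' @param path Path to the data file (UTF-8).
#' @inheritParams parse_data
#' @return An `smw_recordset`.
#' @export
read_data <- function(path, schema, category) {
  parse_data(readLines(path, encoding = "UTF-8", warn = FALSE),
             schema, category)
}
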