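#' Parse the enriched TSV schema dialect
#'
#' The dialect encodes a full site specification in a spreadsheet-friendly
#' tab-separated file:
#'
#' * directive lines start with `!`:
#'   * `!site<TAB>Title[<TAB>lang=xx]` sets the site title and language;
#'   * `!category<TAB>Name[<TAB>parent=P][<TAB>connection=Prop->Target]`
#'     declares a category, optionally a subclass of `P`, optionally linked
#'     to a parent category by the one-to-many connection property `Prop`
#'     (for example each visit page points to its patient page);
#'   * `!group<TAB>Name` opens a property group (a form / drilldown section);
#' * any other non-empty line is a property row
#'   `label<TAB>type<TAB>constraint<TAB>unit<TAB>note[<TAB>aspects]`, attached
#'   to the most recently declared category. The constraint cell is
#'   `min:max` (numeric or date range), `v1|v2|v3` (categorical domain) or
#'   `->Category` (page target); the aspects cell is
#'   `relation=value; relation=value` with relations drawn from
#'   `aspect_vocab`;
#' * lines starting with `#` are comments; an optional header line
#'   (`label<TAB>type...`) is skipped; a UTF-8 BOM is tolerated.
#'
#' Type keywords (case-insensitive): `text`, `number`, `date`, `boolean`,
#' `tristate`, `enum`, `page`, `coordinates`, `url`.
#'
#' Parsing is total: malformed input never raises an error; problems are
#' collected as line-addressed diagnostics retrievable with
#' [schema_diagnostics()], and [validate_schema()] re-checks all semantic
#' invariants. A schema that carries `ERROR` diagnostics is rejected by the
#' emitters.
#'
#' @param text The schema source as a single string, or a character vector of
#'   lines.
#' @param aspect_vocab Allowed aspect relation names
#'   (default [ASPECT_VOCABULARY]).
#' @return An object of class `smw_schema`.
#' @seealso [validate_schema()], [serialize_schema()], [read_schema()]
#' @export
parse_schema <- function(text, aspect_vocab = ASPECT_VOCABULARY) {
  diags <- diag_new()
  if (!all(validUTF8(text))) {
    text <- iconv(text, "UTF-8", "UTF-8", sub = "byte")
    diags <- diag_add(diags, "ERROR", 1L, "input is not valid UTF-8")
  }
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\r?\n")[[1]]
  if (length(text) == 0L) text <- ""
  text[1] <- sub("^﻿", "", text[1])
  schema <- new_schema(aspect_vocab = aspect_vocab)
  cur_cat <- NULL   # index into schema$categories
  cur_group <- ""

  flush_cat <- function() invisible(NULL)  # categories edited in place below

  for (i in seq_along(text)) {
    line <- text[i]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    cells <- strsplit(line, "\t", fixed = TRUE)[[1]]
    cells <- c(cells, rep("", max(0L, 6L - length(cells))))
    cells <- trimws(cells)

    if (startsWith(cells[1], "!")) {
      word <- tolower(cells[1])
      if (word == "!site") {
        if (!nzchar(cells[2])) {
          diags <- diag_add(diags, "ERROR", i, "!site directive needs a title")
          next
        }
        schema$site_title <- cells[2]
        for (extra in cells[-(1:2)]) {
          if (grepl("^lang=", extra))
            schema$language <- sub("^lang=", "", extra)
          else if (nzchar(extra))
            diags <- diag_add(diags, "WARNING", i,
                              sprintf("unknown !site option '%s'", extra))
        }
      } else if (word == "!category") {
        name <- cells[2]
        if (!nzchar(name)) {
          diags <- diag_add(diags, "ERROR", i,
                            "!category directive needs a name")
          next
        }
        cat_ <- new_category(name, line = i)
        bad <- FALSE
        for (extra in cells[-(1:2)]) {
          if (!nzchar(extra)) next
          if (grepl("^parent=", extra)) {
            cat_$parent <- sub("^parent=", "", extra)
          } else if (grepl("^connection=", extra)) {
            m <- regmatches(extra,
                            regexec("^connection=([^>]+)->(.+)$", extra))[[1]]
            if (length(m) == 3L) {
              cat_$connection <- list(property = trimws(m[2]),
                                      target = trimws(m[3]))
            } else {
              diags <- diag_add(diags, "ERROR", i,
                                sprintf("malformed connection '%s' (expected Prop->Target)",
                                        extra))
              bad <- TRUE
            }
          } else {
            diags <- diag_add(diags, "ERROR", i,
                              sprintf("unknown !category option '%s'", extra))
            bad <- TRUE
          }
        }
        schema$categories[[length(schema$categories) + 1L]] <- cat_
        cur_cat <- length(schema$categories)
        cur_group <- ""
      } else if (word == "!group") {
        if (is.null(cur_cat)) {
          diags <- diag_add(diags, "ERROR", i,
                            "!group before any !category")
          next
        }
        if (!nzchar(cells[2])) {
          diags <- diag_add(diags, "ERROR", i, "!group directive needs a name")
          next
        }
        if (cells[2] == "-") {   # `!group<TAB>-` returns to the ungrouped section
          cur_group <- ""
          next
        }
        cur_group <- cells[2]
        g <- schema$categories[[cur_cat]]$groups
        if (!(cur_group %in% g))
          schema$categories[[cur_cat]]$groups <- c(g, cur_group)
      } else {
        diags <- diag_add(diags, "ERROR", i,
                          sprintf("unknown directive '%s'", cells[1]))
      }
      next
    }

    # optional header line
    if (tolower(cells[1]) == "label" && tolower(cells[2]) == "type") next

    if (is.null(cur_cat)) {
      diags <- diag_add(diags, "ERROR", i,
                        "property row before any !category directive")
      next
    }

    parsed <- parse_property_row(cells, i, aspect_vocab)
    diags <- rbind(diags, parsed$diagnostics)
    if (is.null(parsed$property)) next
    p <- parsed$property
    p$category <- schema$categories[[cur_cat]]$name
    p$group <- cur_group
    np <- length(schema$categories[[cur_cat]]$properties)
    schema$categories[[cur_cat]]$properties[[np + 1L]] <- p
  }

  attr(schema, "diagnostics") <- diags
  schema
}

# One property row -> list(property = smw_property or NULL, diagnostics).
parse_property_row <- function(cells, line, aspect_vocab) {
  diags <- diag_new()
  label <- cells[1]
  type_kw <- toupper(cells[2])
  fail <- function(msg) {
    list(property = NULL, diagnostics = diag_add(diags, "ERROR", line, msg))
  }

  if (!nzchar(label)) return(fail("property row with empty label"))
  if (!type_kw %in% names(SMW_TYPES))
    return(fail(sprintf("unknown type keyword '%s' for property '%s'",
                        cells[2], label)))

  cons <- parse_constraint(cells[3], type_kw)
  if (is.character(cons)) return(fail(sprintf("property '%s': %s", label, cons)))

  aspects <- character()
  if (nzchar(cells[6])) {
    pairs <- trimws(strsplit(cells[6], ";", fixed = TRUE)[[1]])
    pairs <- pairs[nzchar(pairs)]
    for (pr in pairs) {
      m <- regmatches(pr, regexec("^([^=]+)=(.*)$", pr))[[1]]
      if (length(m) != 3L || !nzchar(trimws(m[3])))
        return(fail(sprintf("property '%s': malformed aspect '%s'", label, pr)))
      rel <- trimws(m[2]); val <- trimws(m[3])
      if (!rel %in% aspect_vocab)
        return(fail(sprintf(
          "property '%s': aspect relation '%s' not in vocabulary (%s)",
          label, rel, paste(aspect_vocab, collapse = ", "))))
      aspects[[rel]] <- val
    }
  }

  p <- tryCatch(
    new_property(label, type_kw, cons, unit = cells[4], note = cells[5],
                 aspects = aspects, line = line),
    error = function(e) conditionMessage(e)
  )
  if (is.character(p)) return(fail(sprintf("property '%s': %s", label, p)))
  list(property = p, diagnostics = diags)
}

# Returns an smw_constraint, or a character error message.
parse_constraint <- function(cell, type_kw) {
  if (!nzchar(cell)) {
    if (type_kw == "TRISTATE")
      return(new_constraint("DOMAIN", values = TRISTATE_DOMAIN))
    if (type_kw == "ENUM")
      return("ENUM requires a domain constraint (v1|v2|...)")
    if (type_kw == "PAGE")
      return("PAGE requires a target constraint (->Category)")
    return(new_constraint("NONE"))
  }
  if (startsWith(cell, "->")) {
    if (type_kw != "PAGE")
      return(sprintf("target constraint '%s' only valid for PAGE", cell))
    tgt <- trimws(sub("^->", "", cell))
    if (!nzchar(tgt)) return("empty target category")
    return(new_constraint("TARGET", target = tgt))
  }
  if (grepl("|", cell, fixed = TRUE) || type_kw %in% c("ENUM", "TRISTATE")) {
    vals <- trimws(strsplit(cell, "|", fixed = TRUE)[[1]])
    if (type_kw == "TRISTATE") {
      if (!identical(vals, TRISTATE_DOMAIN))
        return(sprintf("TRISTATE domain must be exactly %s",
                       paste(TRISTATE_DOMAIN, collapse = "|")))
      return(new_constraint("DOMAIN", values = TRISTATE_DOMAIN))
    }
    if (type_kw != "ENUM")
      return(sprintf("domain constraint '%s' only valid for ENUM", cell))
    if (any(!nzchar(vals))) return("empty value in domain")
    return(new_constraint("DOMAIN", values = vals))
  }
  if (grepl("^[^:]+:[^:]+$", cell)) {
    parts <- trimws(strsplit(cell, ":", fixed = TRUE)[[1]])
    if (type_kw == "NUMBER") {
      lo <- suppressWarnings(as.numeric(parts[1]))
      hi <- suppressWarnings(as.numeric(parts[2]))
      if (is.na(lo) || is.na(hi))
        return(sprintf("malformed numeric range '%s'", cell))
      return(new_constraint("RANGE", min = lo, max = hi))
    }
    if (type_kw == "DATE") {
      lo <- parse_iso_date(parts[1]); hi <- parse_iso_date(parts[2])
      if (is.na(lo) || is.na(hi))
        return(sprintf("malformed date range '%s' (expected ISO-8601)", cell))
      return(new_constraint("RANGE", min = as.numeric(lo), max = as.numeric(hi)))
    }
    return(sprintf("range constraint '%s' only valid for NUMBER or DATE", cell))
  }
  sprintf("malformed constraint cell '%s'", cell)
}

parse_iso_date <- function(s) {
  if (!grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", s)) return(as.Date(NA))
  suppressWarnings(as.Date(s, format = "%Y-%m-%d"))
}

#' Retrieve the diagnostics collected while parsing a schema
#' @param schema A parsed `smw_schema`.
#' @return A diagnostics data frame (`severity`, `line`, `message`).
#' @export
schema_diagnostics <- function(schema) {
  attr(schema, "diagnostics") %||% diag_new()
}

#' Read and parse a schema TSV file
#' @param path Path to the schema file (UTF-8).
#' @inheritParams parse_schema
#' @return An `smw_schema`.
#' @export
read_schema <- function(path, aspect_vocab = ASPECT_VOCABULARY) {
  parse_schema(readLines(path, encoding = "UTF-8", warn = FALSE),
               aspect_vocab = aspect_vocab)
}

#' Validate a schema against all structural invariants
#'
#' Checks, without mutating its input: at least one category; unique category
#' names; unique property labels per category; resolvable and acyclic
#' subclass hierarchy; connection targets declared and different from the
#' declaring category; ordered numeric ranges; non-empty distinct categorical
#' domains; resolvable page targets; the canonical `Yes`/`No`/`NA` domain on
#' three-valued properties; and valid page titles throughout. Parse-time
#' diagnostics are included in the result.
#'
#' @param schema An `smw_schema`.
#' @return A diagnostics data frame; zero rows means the schema is valid.
#' @export
validate_schema <- function(schema) {
  d <- schema_diagnostics(schema)
  cats <- category_names(schema)

  if (length(schema$categories) == 0L) {
    d <- diag_add(d, "ERROR", 1L, "schema declares no category (at least one required)")
    return(d)
  }
  dup <- unique(cats[duplicated(cats)])
  for (nm in dup)
    d <- diag_add(d, "ERROR", get_category(schema, nm)$line %||% 1L,
                  sprintf("duplicate category name '%s'", nm))

  for (c in schema$categories) {
    ln <- c$line %||% 1L
    if (!is.na(c$parent) && !(c$parent %in% cats))
      d <- diag_add(d, "ERROR", ln,
                    sprintf("category '%s': unresolved reference to parent '%s'",
                            c$name, c$parent))
    if (!is.null(c$connection)) {
      if (!(c$connection$target %in% cats))
        d <- diag_add(d, "ERROR", ln,
                      sprintf("category '%s': unresolved reference to connection target '%s'",
                              c$name, c$connection$target))
      if (identical(c$connection$target, c$name))
        d <- diag_add(d, "ERROR", ln,
                      sprintf("category '%s': connection target must differ from the category itself",
                              c$name))
      ok <- tryCatch({property_page_name(c$connection$property); TRUE},
                     error = function(e) FALSE)
      if (!ok)
        d <- diag_add(d, "ERROR", ln,
                      sprintf("category '%s': invalid connection property name",
                              c$name))
    }
    labs <- vapply(c$properties, `[[`, character(1), "label")
    for (nm in unique(labs[duplicated(labs)]))
      d <- diag_add(d, "ERROR", ln,
                    sprintf("category '%s': duplicate property label '%s'",
                            c$name, nm))
    for (p in c$properties) {
      pl <- p$line %||% ln
      k <- p$constraint$kind
      if (k == "RANGE" && !(p$constraint$min <= p$constraint$max))
        d <- diag_add(d, "ERROR", pl,
                      sprintf("property '%s': range min %s exceeds max %s",
                              p$label, num_chr(p$constraint$min),
                              num_chr(p$constraint$max)))
      if (k == "DOMAIN") {
        v <- p$constraint$values
        if (length(v) < 1L || any(!nzchar(v)) || anyDuplicated(v))
          d <- diag_add(d, "ERROR", pl,
                        sprintf("property '%s': domain must list distinct non-empty values",
                                p$label))
      }
      if (k == "TARGET" && !(p$constraint$target %in% cats))
        d <- diag_add(d, "ERROR", pl,
                      sprintf("property '%s': unresolved reference to target category '%s'",
                              p$label, p$constraint$target))
      if (p$type == "TRISTATE" &&
          !(k == "DOMAIN" && identical(p$constraint$values, TRISTATE_DOMAIN)))
        d <- diag_add(d, "ERROR", pl,
                      sprintf("property '%s': three-valued properties must use the %s domain",
                              p$label, paste(TRISTATE_DOMAIN, collapse = "/")))
      if (length(p$aspects) &&
          !all(names(p$aspects) %in% schema$aspect_vocab))
        d <- diag_add(d, "ERROR", pl,
                      sprintf("property '%s': aspect relation outside the vocabulary",
                              p$label))
    }
  }

  # subclass hierarchy must be acyclic
  parent_of <- stats::setNames(
    vapply(schema$categories, `[[`, character(1), "parent"), cats)
  for (start in cats) {
    seen <- character()
    node <- start
    while (!is.na(node) && node %in% cats) {
      if (node %in% seen) {
        if (node == start)
          d <- diag_add(d, "ERROR", get_category(schema, start)$line %||% 1L,
                        sprintf("subclass hierarchy cycle through '%s'", start))
        break
      }
      seen <- c(seen, node)
      node <- parent_of[[node]]
    }
  }
  d
}

#' Is a schema free of errors?
#' @param schema An `smw_schema`.
#' @return `TRUE` when [validate_schema()] reports no `ERROR` diagnostics.
#' @export
schema_ok <- function(schema) {
  nrow(diag_errors(validate_schema(schema))) == 0L
}

stop_if_invalid <- function(schema) {
  d <- diag_errors(validate_schema(schema))
  if (nrow(d) > 0L)
    stop("invalid schema:\n",
         paste(sprintf("  line %d: %s", d$line, d$message), collapse = "\n"),
         call. = FALSE)
  invisible(schema)
}
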