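ASK_COMPARATORS <- c(EQ = "", GT = ">", GE = ">=", LT = "<", LE = "<=",
                     LIKE = "~")
ORDERED_TYPES <- c("NUMBER", "DATE")

new_ask <- function(category, conditions = list(), printouts = list()) {
  structure(list(category = category, conditions = conditions,
                 printouts = printouts),
            class = "smw_ask")
}

# The category a chain leads to, walking connection/page edges from `from`.
chain_endpoint <- function(schema, from, chain) {
  cur <- from
  if (nrow(chain) == 0L) return(cur)
  g <- schema_graph(schema)
  for (k in seq_len(nrow(chain))) {
    p <- chain$property[k]
    if (chain$direction[k] == "FORWARD") {
      sel <- g$edges$from == cur & g$edges$property == p
    } else {
      sel <- g$edges$to == cur & g$edges$property == p
    }
    if (!any(sel))
      stop(sprintf("chain step '%s' is not an edge at category '%s'", p, cur))
    cur <- if (chain$direction[k] == "FORWARD") g$edges$to[which(sel)[1]]
    else g$edges$from[which(sel)[1]]
  }
  cur
}

resolve_property <- function(schema, g, category, label) {
  chain <- resolve_chain(g, category, label)
  owner <- chain_endpoint(schema, category, chain)
  p <- get_property(get_category(schema, owner), label)
  list(chain = chain, property = p)
}

#' Construct an ASK query with automatic property-chain resolution
#'
#' The user names only the reference category, the conditions and the
#' projected properties ("printouts"); properties that live on related
#' categories are reached automatically through the shortest chain of
#' (possibly inverse) connection steps, mirroring the chain auto-completion
#' a query assistant provides.
#'
#' @param schema A valid `smw_schema`.
#' @param category Reference category selecting the result entities.
#' @param conditions A list of `list(property =, comparator =, value =)`
#'   entries; comparators are `EQ`, `GT`, `GE`, `LT`, `LE`, `LIKE`
#'   (order comparators only for numbers and dates).
#' @param printouts Character vector of property labels to project.
#' @return An `smw_ask` object.
#' @examples
#' s <- parse_schema(paste(
#'   "!category\tPatients", "Age\tnumber\t0:120",
#'   "!category\tVisits\tconnection=Has Patient->Patients",
#'   "Temperature\tnumber\t30:45\t°C", sep = "\n"))
#' q <- ask_query(s, "Visits",
#'                conditions = list(list(property = "Temperature",
#'                                       comparator = "GT", value = 37)),
#'                printouts = "Temperature")
#' build_ask(q, s)
#' @export
ask_query <- function(schema, category, conditions = list(),
                      printouts = character()) {
  stop_if_invalid(schema)
  if (is.null(get_category(schema, category)))
    stop(sprintf("unknown category '%s'", category))
  g <- schema_graph(schema)
  conds <- lapply(conditions, function(cd) {
    stopifnot(!is.null(cd$property), !is.null(cd$comparator),
              !is.null(cd$value))
    if (!cd$comparator %in% names(ASK_COMPARATORS))
      stop(sprintf("unknown comparator '%s'", cd$comparator))
    res <- resolve_property(schema, g, category, cd$property)
    if (cd$comparator %in% c("GT", "GE", "LT", "LE") &&
        !res$property$type %in% ORDERED_TYPES)
      stop(sprintf("comparator %s requires a number or date property, but '%s' is %s",
                   cd$comparator, cd$property, res$property$type))
    value <- cd$value
    if (res$property$type == "DATE" && is.character(value)) {
      value <- parse_iso_date(value)
      if (is.na(value)) stop("malformed ISO date operand")
    }
    if (res$property$type == "NUMBER" && is.character(value)) {
      value <- suppressWarnings(as.numeric(value))
      if (is.na(value)) stop("malformed numeric operand")
    }
    list(chain = res$chain, property = cd$property,
         comparator = cd$comparator, value = value)
  })
  prints <- lapply(printouts, function(lab) {
    res <- resolve_property(schema, g, category, lab)
    list(chain = res$chain, property = lab)
  })
  new_ask(category, conds, prints)
}

render_lhs <- function(chain, label) {
  pre <- render_chain(chain)
  paste0(if (nzchar(pre)) paste0(pre, ".") else "", property_page_name(label))
}

#' Render an ASK query as wikitext
#'
#' Produces the inline query text, e.g.
#' `{{#ask: [[Category:Visits]] [[Temperature::>37]] |?Temperature}}`;
#' chains render dot-separated with a `-` prefix on inverse steps, strict
#' comparators as `>`/`<` and inclusive ones as `>=`/`<=`.
#'
#' @param q An `smw_ask`, typically from [ask_query()].
#' @param schema The schema the query addresses.
#' @return A single string, byte-stable across runs.
#' @export
build_ask <- function(q, schema) {
  g <- schema_graph(schema)
  parts <- sprintf("[[Category:%s]]", property_page_name(q$category))
  for (cd in q$conditions) {
    owner <- chain_endpoint(schema, q$category, cd$chain)
    p <- get_property(get_category(schema, owner), cd$property)
    if (is.null(p))
      stop(sprintf("condition chain does not lead to property '%s'",
                   cd$property))
    parts <- c(parts, sprintf("[[%s::%s%s]]", render_lhs(cd$chain, cd$property),
                              ASK_COMPARATORS[[cd$comparator]],
                              encode_value(cd$value, p)))
  }
  prints <- vapply(q$printouts, function(po)
    paste0("|?", render_lhs(po$chain, po$property)), character(1))
  paste0("{{#ask: ", paste(parts, collapse = " "),
         if (length(prints)) paste0(" ", paste(prints, collapse = " ")) else "",
         "}}")
}

#' Parse rendered ASK query text back into a query object
#'
#' Inverse of [build_ask()] for the dialect this package emits; used to check
#' printer/parser consistency.
#'
#' @param text Query wikitext.
#' @param schema The schema the query addresses.
#' @return An `smw_ask`.
#' @export
parse_ask <- function(text, schema) {
  m <- regmatches(text, regexec(
    "^\\{\\{#ask: \\[\\[Category:([^]]+)\\]\\]((?: \\[\\[[^]]+\\]\\])*)((?: \\|\\?[^|}]+)*)\\}\\}$",
    text))[[1]]
  if (length(m) != 4L) stop("unrecognized ask query text")
  category <- find_category_by_page_name(schema, m[2])
  conds <- list()
  for (c_txt in regmatches(m[3], gregexpr("\\[\\[[^]]+\\]\\]", m[3]))[[1]]) {
    inner <- sub("^\\[\\[", "", sub("\\]\\]$", "", c_txt))
    kv <- regmatches(inner, regexec("^(.*?)::(.*)$", inner))[[1]]
    lhs <- parse_lhs(schema, category, kv[2])
    rhs <- kv[3]
    cmp <- "EQ"
    for (nm in c("GE", "LE", "GT", "LT", "LIKE")) {
      sym <- ASK_COMPARATORS[[nm]]
      if (startsWith(rhs, sym)) {
        cmp <- nm; rhs <- substring(rhs, nchar(sym) + 1L); break
      }
    }
    conds[[length(conds) + 1L]] <-
      list(chain = lhs$chain, property = lhs$label, comparator = cmp,
           value = decode_value(rhs, lhs$property))
  }
  prints <- list()
  for (p_txt in regmatches(m[4], gregexpr("\\|\\?[^|}]+", m[4]))[[1]]) {
    lhs <- parse_lhs(schema, category, trimws(sub("^\\|\\?", "", p_txt)))
    prints[[length(prints) + 1L]] <- list(chain = lhs$chain,
                                          property = lhs$label)
  }
  new_ask(category, conds, prints)
}

find_category_by_page_name <- function(schema, page_name) {
  for (c in schema$categories)
    if (property_page_name(c$name) == page_name) return(c$name)
  stop(sprintf("unknown category page '%s'", page_name))
}

parse_lhs <- function(schema, category, lhs) {
  segs <- strsplit(lhs, ".", fixed = TRUE)[[1]]
  chain <- if (length(segs) > 1L)
    parse_chain(paste(segs[-length(segs)], collapse = "."))
  else new_chain()
  owner <- chain_endpoint(schema, category, chain)
  pn <- segs[length(segs)]
  for (p in get_category(schema, owner)$properties)
    if (p$page_name == pn)
      return(list(chain = chain, label = p$label, property = p))
  stop(sprintf("no property page '%s' on category '%s'", pn, owner))
}

# --- reference evaluator ----------------------------------------------------

value_satisfies <- function(v, comparator, operand, type) {
  if (is.null(v)) return(FALSE)  # MISSING never satisfies a comparator
  if (type %in% ORDERED_TYPES) {
    x <- as.numeric(v); y <- as.numeric(operand)
    return(switch(comparator,
                  EQ = isTRUE(x == y), GT = isTRUE(x > y),
                  GE = isTRUE(x >= y), LT = isTRUE(x < y),
                  LE = isTRUE(x <= y),
                  LIKE = grepl(utils::glob2rx(as.character(operand)),
                               as.character(v))))
  }
  switch(comparator,
         EQ = identical(as.character(v), as.character(operand)),
         LIKE = grepl(utils::glob2rx(as.character(operand)),
                      as.character(v)),
         FALSE)
}

# All records reachable from `r` along `chain` (existential semantics).
follow_chain <- function(rs, index, r, chain) {
  cur <- list(r)
  for (k in seq_len(nrow(chain))) {
    p <- chain$property[k]
    nxt <- list()
    for (rec in cur) {
      if (chain$direction[k] == "FORWARD") {
        cat_ <- get_category(rs$schema, rec$category)
        if (!is.null(cat_$connection) && cat_$connection$property == p) {
          if (!is.na(rec$parent_title) &&
              !is.null(index$by_title[[rec$parent_title]]))
            nxt <- c(nxt, list(index$by_title[[rec$parent_title]]))
        } else if (!is.null(rec$values[[p]]) &&
                   !is.null(index$by_title[[rec$values[[p]]]])) {
          nxt <- c(nxt, list(index$by_title[[rec$values[[p]]]]))
        }
      } else {
        key <- paste0(p, "\r", rec$title)
        nxt <- c(nxt, index$children[[key]] %||% list())
      }
    }
    cur <- nxt
  }
  cur
}

build_record_index <- function(rs) {
  by_title <- list()
  children <- list()
  for (r in rs$records) {
    if (!is.na(r$title)) by_title[[r$title]] <- r
    cat_ <- get_category(rs$schema, r$category)
    if (!is.null(cat_$connection) && !is.na(r$parent_title)) {
      key <- paste0(cat_$connection$property, "\r", r$parent_title)
      children[[key]] <- c(children[[key]], list(r))
    }
    for (p in cat_$properties) {
      if (p$type == "PAGE" && !is.null(r$values[[p$label]])) {
        key <- paste0(p$label, "\r", r$values[[p$label]])
        children[[key]] <- c(children[[key]], list(r))
      }
    }
  }
  list(by_title = by_title, children = children)
}

#' Evaluate an ASK query over a record set
#'
#' A reference evaluator with the semantics a wiki would apply: result rows
#' are the entities of the query's category for which every condition is
#' satisfied by at least one record reached along its chain (parent links
#' followed forward, child links inversely); MISSING cells never satisfy a
#' comparator, while the explicit three-valued `"NA"` is an ordinary value
#' that `EQ "NA"` selects. Printout columns collect the reached values.
#'
#' @param q An `smw_ask`.
#' @param rs An `smw_recordset` bound to the same schema, titles assigned.
#' @return A data frame: `Entity` plus one column per printout (multiple
#'   reached values joined by `"; "`, empty string when none).
#' @export
evaluate_ask <- function(q, rs) {
  index <- build_record_index(rs)
  schema <- rs$schema
  hits <- Filter(function(r) {
    r$category == q$category &&
      all(vapply(q$conditions, function(cd) {
        owner <- chain_endpoint(schema, q$category, cd$chain)
        p <- get_property(get_category(schema, owner), cd$property)
        any(vapply(follow_chain(rs, index, r, cd$chain), function(rec)
          value_satisfies(rec$values[[cd$property]], cd$comparator,
                          cd$value, p$type), logical(1)))
      }, logical(1)))
  }, rs$records)
  out <- data.frame(Entity = vapply(hits, `[[`, character(1), "title"),
                    stringsAsFactors = FALSE)
  for (po in q$printouts) {
    owner <- chain_endpoint(schema, q$category, po$chain)
    p <- get_property(get_category(schema, owner), po$property)
    col <- vapply(hits, function(r) {
      vals <- Filter(Negate(is.null),
                     lapply(follow_chain(rs, index, r, po$chain),
                            function(rec) rec$values[[po$property]]))
      paste(vapply(vals, encode_value, character(1), p = p), collapse = "; ")
    }, character(1))
    out[[paste0("?", render_lhs(po$chain, po$property))]] <- col
  }
  out
}

#' JSON form of an ASK query (for tooling)
#' @param q An `smw_ask`.
#' @return A JSON string.
#' @export
ask_to_json <- function(q) {
  jsonlite::toJSON(list(
    category = q$category,
    conditions = lapply(q$conditions, function(cd)
      list(chain = render_chain(cd$chain), property = cd$property,
           comparator = cd$comparator,
           value = as.character(cd$value))),
    printouts = lapply(q$printouts, function(po)
      list(chain = render_chain(po$chain), property = po$property))
  ), auto_unbox = TRUE, pretty = TRUE)
}
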