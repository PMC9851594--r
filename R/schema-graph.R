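#' Build the category graph of a schema
#'
#' One node per category; one directed edge per one-to-many connection
#' (child category to its parent category, labeled with the connection
#' property) and one per page-typed property (to its target category).
#' Queries traverse edges in both directions: following an edge against its
#' direction is an *inverse* step, rendered with a leading minus sign.
#'
#' @param schema A valid `smw_schema`.
#' @return An object of class `smw_graph` with elements `nodes` (character),
#'   `edges` (data frame `from`, `to`, `property`) and `owners` (named list
#'   mapping property labels to the categories that declare them).
#' @export
schema_graph <- function(schema) {
  stop_if_invalid(schema)
  nodes <- category_names(schema)
  from <- character(); to <- character(); prop <- character()
  owners <- list()
  for (c in schema$categories) {
    if (!is.null(c$connection)) {
      from <- c(from, c$name); to <- c(to, c$connection$target)
      prop <- c(prop, c$connection$property)
    }
    for (p in c$properties) {
      owners[[p$label]] <- c(owners[[p$label]], c$name)
      if (p$type == "PAGE" && p$constraint$kind == "TARGET") {
        from <- c(from, c$name); to <- c(to, p$constraint$target)
        prop <- c(prop, p$label)
      }
    }
  }
  structure(list(
    nodes = nodes,
    edges = data.frame(from = from, to = to, property = prop,
                       stringsAsFactors = FALSE),
    owners = owners
  ), class = "smw_graph")
}

new_chain <- function(property = character(), direction = character()) {
  structure(data.frame(property = property, direction = direction,
                       stringsAsFactors = FALSE),
            class = c("smw_chain", "data.frame"))
}

#' Render a property chain
#'
#' Steps are joined by `.`; inverse steps carry a `-` prefix
#' (e.g. `-Has Patient.Has Centre`). The empty chain renders as `""`.
#'
#' @param chain An `smw_chain`.
#' @return A single string.
#' @export
render_chain <- function(chain) {
  if (nrow(chain) == 0L) return("")
  paste(paste0(ifelse(chain$direction == "INVERSE", "-", ""),
               chain$property), collapse = ".")
}

#' Parse a rendered chain back into steps
#' @param text A chain rendering such as `"-Has Patient.Has Centre"`.
#' @return An `smw_chain`.
#' @export
parse_chain <- function(text) {
  if (!nzchar(text)) return(new_chain())
  steps <- strsplit(text, ".", fixed = TRUE)[[1]]
  inv <- startsWith(steps, "-")
  new_chain(property = sub("^-", "", steps),
            direction = ifelse(inv, "INVERSE", "FORWARD"))
}

#' Resolve the property chain from a category to a property
#'
#' The auto-completion core: given a starting category and a property label
#' that may live on a related category, find the shortest path of connection
#' steps (forward or inverse) leading from the starting category to the
#' category that declares the property. A property declared on the starting
#' category itself resolves to the empty chain.
#'
#' Ambiguities are handled deterministically: if two different categories at
#' the same minimal distance both declare the label, resolution fails with an
#' error listing the candidates; if several equally short paths reach the one
#' owning category, the lexicographically smallest rendered chain is chosen
#' and a warning is emitted.
#'
#' @param g An `smw_graph` from [schema_graph()].
#' @param from_cat Name of the starting category.
#' @param prop A property label declared somewhere in the schema.
#' @return An `smw_chain`.
#' @export
resolve_chain <- function(g, from_cat, prop) {
  if (!from_cat %in% g$nodes)
    stop(sprintf("unknown category '%s'", from_cat))
  owners <- g$owners[[prop]]
  if (is.null(owners))
    stop(sprintf("no category declares property '%s'", prop))
  if (from_cat %in% owners) return(new_chain())

  dist <- graph_distances(g, from_cat)
  reach <- owners[is.finite(dist[owners])]
  if (length(reach) == 0L)
    stop(sprintf("property '%s' is not reachable from category '%s'",
                 prop, from_cat))
  dmin <- min(dist[reach])
  nearest <- reach[dist[reach] == dmin]
  if (length(nearest) > 1L)
    stop(sprintf(
      "property '%s' is ambiguous from '%s': declared at equal distance by %s",
      prop, from_cat, paste(sort_c(nearest), collapse = ", ")))

  paths <- shortest_paths_to(g, dist, nearest)
  rendered <- vapply(paths, render_chain, character(1))
  o <- order_c(rendered)
  if (length(unique(rendered)) > 1L)
    warning(sprintf(
      "several equally short chains reach '%s' from '%s'; choosing '%s'",
      prop, from_cat, rendered[o[1]]))
  paths[[o[1]]]
}

# Undirected BFS distances from `from`, in steps, over the connection graph.
graph_distances <- function(g, from) {
  dist <- stats::setNames(rep(Inf, length(g$nodes)), g$nodes)
  dist[from] <- 0
  frontier <- from
  while (length(frontier)) {
    nxt <- character()
    for (node in frontier) {
      fwd <- g$edges$to[g$edges$from == node]
      inv <- g$edges$from[g$edges$to == node]
      for (nb in c(fwd, inv)) {
        if (!is.finite(dist[nb])) {
          dist[nb] <- dist[node] + 1
          nxt <- c(nxt, nb)
        }
      }
    }
    frontier <- unique(nxt)
  }
  dist
}

# Enumerate every shortest path (as an smw_chain) from the BFS source to
# `target`, walking the distance labels backwards.
shortest_paths_to <- function(g, dist, target) {
  walk <- function(node) {
    if (dist[node] == 0) return(list(new_chain()))
    out <- list()
    # predecessor via a FORWARD step: edge pred -> node with dist[pred]+1 == dist[node]
    sel <- g$edges$to == node & is.finite(dist[g$edges$from]) &
      dist[g$edges$from] == dist[node] - 1
    for (k in which(sel)) {
      for (pre in walk(g$edges$from[k]))
        out <- c(out, list(rbind_chain(pre, g$edges$property[k], "FORWARD")))
    }
    # predecessor via an INVERSE step: edge node -> pred traversed backwards
    sel <- g$edges$from == node & is.finite(dist[g$edges$to]) &
      dist[g$edges$to] == dist[node] - 1
    for (k in which(sel)) {
      for (pre in walk(g$edges$to[k]))
        out <- c(out, list(rbind_chain(pre, g$edges$property[k], "INVERSE")))
    }
    out
  }
  walk(target)
}

rbind_chain <- function(chain, property, direction) {
  new_chain(c(chain$property, property), c(chain$direction, direction))
}
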