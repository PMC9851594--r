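# Shared fixtures and independent oracles, all built in code.

fixture_pv_text <- function() {
  paste(
    "!category\tPatients",
    "Age\tnumber\t0:120",
    "!category\tVisits\tconnection=Has Patient->Patients",
    "Temperature\tnumber\t30:45\t°C",
    sep = "\n")
}

fixture_pv <- function() parse_schema(fixture_pv_text())

fixture_covid <- function() {
  read_schema(system.file("extdata", "covid_schema.tsv",
                          package = "smwbuilder"))
}

fixture_audiology <- function() {
  read_schema(system.file("extdata", "audiology_schema.tsv",
                          package = "smwbuilder"))
}

AUDIOLOGY_LABEL <- paste("Pure tone average of vocal gain during last",
                         "control exam with intracochlear device on left ear")

n_errors <- function(diags) sum(diags$severity == "ERROR")

diag_msg <- function(diags) {
  paste(diags$message[diags$severity == "ERROR"], collapse = " | ")
}

# --- random schema generator (seeded by the caller) -------------------------

random_schema_text <- function(n_categories = sample(1:3, 1)) {
  types <- c("text", "number", "date", "boolean", "tristate", "enum",
             "coordinates", "url")
  lines <- c(sprintf("!site\tRandom site %d\tlang=en", sample(999, 1)))
  plab <- 0L
  for (ci in seq_len(n_categories)) {
    head <- sprintf("!category\tCat%d", ci)
    if (ci > 1L)
      head <- sprintf("%s\tconnection=Link %d->Cat%d", head, ci,
                      sample(ci - 1L, 1))
    lines <- c(lines, head)
    in_group <- FALSE
    for (pi in seq_len(sample(2:6, 1))) {
      if (!in_group && stats::runif(1) < 0.3) {
        lines <- c(lines, sprintf("!group\tGroup %d", ci))
        in_group <- TRUE
      }
      plab <- plab + 1L
      type <- sample(types, 1)
      cons <- switch(type,
        number = if (stats::runif(1) < 0.7) {
          lo <- round(stats::runif(1, 0, 50), 1)
          paste0(lo, ":", round(lo + stats::runif(1, 1, 100), 1))
        } else "",
        date = if (stats::runif(1) < 0.5) "2019-01-01:2021-12-31" else "",
        enum = paste(sample(letters, sample(2:5, 1)), collapse = "|"),
        "")
      unit <- if (type == "number" && stats::runif(1) < 0.3) "mm" else ""
      aspects <- if (stats::runif(1) < 0.15)
        sprintf("laterality=%s; device=%s", sample(c("left", "right"), 1),
                sample(c("probe", "implant"), 1))
      else ""
      lines <- c(lines, paste(sprintf("Prop %d", plab), type, cons, unit,
                              sprintf("note %d", plab), aspects, sep = "\t"))
    }
  }
  paste(lines, collapse = "\n")
}

random_schema <- function(n_categories = sample(1:3, 1)) {
  parse_schema(random_schema_text(n_categories))
}

# Schema whose connection links realize a given parent vector (0 = root);
# category i declares the single property "Prop i".
graph_schema <- function(parents) {
  lines <- character()
  for (i in seq_along(parents)) {
    head <- sprintf("!category\tCat%d", i)
    if (parents[i] > 0L)
      head <- sprintf("%s\tconnection=Link %d->Cat%d", head, i, parents[i])
    lines <- c(lines, head, sprintf("Prop %d\tnumber", i))
  }
  parse_schema(paste(lines, collapse = "\n"))
}

# Category graph built directly from a parent vector (same shape as
# schema_graph output), bypassing the TSV layer for bulk graph tests.
graph_from_parents <- function(parents) {
  n <- length(parents)
  nodes <- sprintf("Cat%d", seq_len(n))
  sel <- which(parents > 0)
  edges <- data.frame(from = nodes[sel], to = nodes[parents[sel]],
                      property = sprintf("Link %d", sel),
                      stringsAsFactors = FALSE)
  owners <- stats::setNames(as.list(nodes), sprintf("Prop %d", seq_len(n)))
  structure(list(nodes = nodes, edges = edges, owners = owners),
            class = "smw_graph")
}

# All parent vectors over n nodes that form a forest (acyclic).
enumerate_forests <- function(n) {
  grids <- do.call(expand.grid, rep(list(0:n), n))
  keep <- apply(grids, 1, function(p) {
    if (any(p == seq_len(n))) return(FALSE)
    for (s in seq_len(n)) {  # follow parents; a cycle revisits s
      seen <- logical(n); node <- s
      while (node != 0L) {
        if (seen[node]) return(FALSE)
        seen[node] <- TRUE
        node <- p[node]
      }
    }
    TRUE
  })
  grids[keep, , drop = FALSE]
}

# Independent shortest-path oracle: exhaustive DFS over all simple paths in
# the undirected connection graph defined by `parents`.
oracle_shortest <- function(parents, from, to) {
  n <- length(parents)
  adj <- vector("list", n)
  for (i in seq_len(n)) if (parents[i] > 0L) {
    adj[[i]] <- c(adj[[i]], parents[i])
    adj[[parents[i]]] <- c(adj[[parents[i]]], i)
  }
  best <- Inf
  dfs <- function(node, visited, depth) {
    if (node == to) { best <<- min(best, depth); return() }
    for (nb in adj[[node]]) if (!visited[nb]) {
      v <- visited; v[nb] <- TRUE
      dfs(nb, v, depth + 1L)
    }
  }
  v <- logical(n); v[from] <- TRUE
  dfs(from, v, 0L)
  best
}

# --- minimal Prolog ground-term parser (loadability oracle) -----------------

# Splits s at top-level commas (outside quotes and parentheses).
.pl_split_args <- function(s) {
  out <- character(); depth <- 0L; inq <- FALSE; buf <- ""
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (inq) {
      if (ch == "'") {
        if (i < length(chars) && chars[i + 1] == "'") {
          buf <- paste0(buf, "''"); i <- i + 2L; next
        }
        inq <- FALSE
      }
      buf <- paste0(buf, ch)
    } else if (ch == "'") { inq <- TRUE; buf <- paste0(buf, ch) }
    else if (ch == "(") { depth <- depth + 1L; buf <- paste0(buf, ch) }
    else if (ch == ")") { depth <- depth - 1L; buf <- paste0(buf, ch) }
    else if (ch == "," && depth == 0L) { out <- c(out, buf); buf <- "" }
    else buf <- paste0(buf, ch)
    i <- i + 1L
  }
  if (inq || depth != 0L) stop("unbalanced quotes or parentheses: ", s)
  trimws(c(out, buf))
}

# Parses one ground term; returns list(kind, value/functor, args).
parse_prolog_term <- function(s) {
  s <- trimws(s)
  if (grepl("^'", s)) {
    if (!grepl("^'([^']|'')*'$", s)) stop("malformed quoted atom: ", s)
    inner <- sub("^'", "", sub("'$", "", s))
    return(list(kind = "atom", value = gsub("''", "'", inner, fixed = TRUE)))
  }
  if (grepl("^-?[0-9]+(\\.[0-9]+)?$", s))
    return(list(kind = "number", value = as.numeric(s)))
  m <- regmatches(s, regexec("^([a-z][a-zA-Z0-9_]*)\\((.*)\\)$", s))[[1]]
  if (length(m) == 3L)
    return(list(kind = "compound", functor = m[2],
                args = lapply(.pl_split_args(m[3]), parse_prolog_term)))
  if (grepl("^[a-z][a-zA-Z0-9_]*$", s))
    return(list(kind = "atom", value = s))
  stop("unparseable term: ", s)
}

# Parses a fact file into a list of clauses (each a compound term); errors
# on any line that is not a comment, blank, or a ground clause.
parse_prolog_program <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  clauses <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "%")) next
    if (!grepl("\\.$", ln)) stop("clause without terminating dot: ", ln)
    term <- parse_prolog_term(sub("\\.$", "", ln))
    if (term$kind != "compound") stop("clause is not a compound term: ", ln)
    clauses[[length(clauses) + 1L]] <- term
  }
  clauses
}
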