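---
title: "Building semantic wiki databases from tabular schemas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building semantic wiki databases from tabular schemas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smwbuilder)
```

## The model

`smwbuilder` treats a Semantic MediaWiki site as the compilation target of a
small relational-ish model:

* a **category** plays the role of a table (and of an OWL class): its
  entities are wiki pages tagged with `[[Category:Name]]`;
* a **property** is a typed column. Each property becomes a
  `Property:`-namespace page carrying exactly one `[[Has type::...]]`
  annotation, and, for categorical domains, one `[[Allows value::v]]` per
  value in declared order;
* a **connection** is a one-to-many foreign key: a `Page`-typed property on
  the child category pointing at the parent (each visit page points at its
  patient page). Connections are what makes cross-category querying
  possible;
* **templates** guarantee annotation uniformity: entity pages never annotate
  directly, they call the category template with named arguments, and the
  template attaches `[[Prop::value]]` for every non-empty argument. Forms
  (PageForms) are generated against the same parameter list, so data entry,
  rendering and annotation can never drift apart;
* **drilldown filters** are declared on the category page for every
  property whose value space is enumerable or bounded (categorical,
  three-valued, boolean, numeric range).

The compiler's central guarantee is *closure*: every property name
referenced by any emitted annotation has a property page in the same
document, so the import is self-contained. The test suite checks this by
scanning the emitted wikitext with the annotation pattern rather than by
trusting the emitter's bookkeeping, and asserts the page inventory formula
`1 + 3·|categories| + |distinct properties ∪ connections ∪ aspect
relations|` on randomized schemas.

## The schema dialect

The input grammar is deliberately typeable in a spreadsheet: directive lines
(`!site`, `!category`, `!group`) interleaved with property rows
`label → type → constraint → unit → note → aspects`. Constraints are
`min:max` for numbers and dates, `v1|v2|v3` for categorical domains and
`->Category` for page targets. Tabs and newlines are structural and
forbidden inside cells; there is no quoting dialect, because every quoting
convention we considered is exactly what non-technical schema authors get
wrong in spreadsheets. UTF-8 is the only encoding; a BOM is tolerated.

Parsing is *total*: any byte string yields either a schema or line-addressed
diagnostics, never an exception (a fuzz test holds this). Semantic
validation (resolvable references, acyclic hierarchy, ordered ranges,
distinct domains, unique labels) is a separate pass returning diagnostics,
so a user sees all problems at once rather than the first one.

A canonical serializer renders a schema back to the dialect;
`parse(serialize(x))` is an identity on structured content and is tested on
the shipped fixtures and on randomized schemas. Property rows keep their
declaration order throughout, because form layout and drilldown grouping are
presentation decisions the schema author already made.

## Three-valued clinical fields

Boolean clinical observations frequently need to distinguish "we asked and
there is no answer" from "nobody has entered this yet". Three-valued
(`tristate`) properties therefore use the fixed domain `Yes`/`No`/`NA`,
where the literal cell `NA` is an ordinary stored value and an empty cell is
MISSING. The tokens themselves are a package convention (the semantics — an
explicit "not available" — is the requirement); fixing them canonically
keeps forms, drilldown filters, queries and Prolog exports agreeing on the
value space. Queries treat the two correctly by construction: `EQ "NA"`
selects exactly the records with the explicit value, while MISSING never
satisfies any comparator.

## Entity naming

Entities are named with progressive numbers (`Patients 7`) rather than
personal details — an abstraction that is both privacy-preserving and
general. Records of a connected category are subpages of their parent
(`Patients 7/Visits 2`, counted per parent): this makes the one-to-many
relation visible in the title, guarantees uniqueness across parents, and
gives the wiki's own subpage navigation something to work with. Since the
wiki's uniqueness constraint only *signals* conflicts, the importer refuses
title collisions outright; `start_index` exists so incremental imports into
a populated site can keep numbering where the last import stopped.

## Chain resolution

Cross-category queries need property chains; composing them by hand
(especially inverse steps) is the most error-prone part of the query
language. `resolve_chain()` does it automatically: BFS over the category
graph, treating every connection edge as traversable forward (child to
parent) or inversely (parent to child, rendered with a `-` prefix), and
returning the shortest chain to the category that declares the requested
property.

Two ambiguity policies, chosen for determinism over silent guessing:

* if two *different* categories at the same minimal distance declare the
  label, resolution fails with an error listing the candidates — no
  tie-break is defensible when the two chains mean different things;
* if several equally short chains reach the *same* owning category, the
  lexicographically smallest rendered chain (byte order) is chosen and a
  warning is emitted — the results are semantically interchangeable, and a
  stable pick keeps query text reproducible.

Correctness is checked against an independent oracle (exhaustive
simple-path enumeration) over every connection forest with up to six
categories and 200 larger random graphs.

## Query text

The builder emits the inline ASK dialect,
`{{#ask: [[Category:Visits]] [[Temperature::>37]] |?Temperature}}`.
Comparator rendering: `GT`/`LT` as bare `>`/`<`, and `GE`/`LE` as the
two-character forms `>=`/`<=` — adjusting the operand instead (e.g. turning
"at least 37.5" into "> 37.49...") would be wrong for arbitrary floats, so
the inclusive forms are kept syntactic. `LIKE` renders as `~` with glob
semantics. The packaged evaluator gives the query language an executable
semantics without a wiki: conditions are existential over the records
reached along the chain, printouts collect the reached values. A
print/parse round-trip test pins the dialect.

## The XML layer

Import documents are pinned to the export-0.10 page-dump dialect with
minimal, fixed revision metadata (one revision per page, fixed contributor
and timestamp). The fixed timestamp is a default argument, not a constant,
but reproducibility is the default: equal schemas must serialize to equal
bytes, and they do (asserted byte-for-byte). A structural validator checks
the dialect's shape — root namespace and version, canonical child order of
`siteinfo`, `page` and `revision`, ISO timestamps, `wikitext`/`text/x-wiki`
revisions, namespace-unique titles — and doubles as the acceptance check on
compiled sites.

## The synthetic data generator

The generator's job is to produce data that is *constraint-true*, not
clinically realistic: uniform draws over ranges, domains, date windows and
coordinate bounding boxes, plus small word/URL pools for free text. Defaults
model a modest patient-visit study: 100 parents, 1–4 child records each, 5%
missing cells, a 2020 date window and an Italy-sized coordinate box (the
shipped demo is a COVID-style surveillance schema). What it deliberately
does **not** emulate: correlated comorbidities, informative missingness,
longitudinal trends, or any joint distribution across columns. Tests passing
on generated data therefore demonstrate structural correctness (parsing,
constraints, round-trips, query semantics), not statistical plausibility.

One design point matters for fixture stability: every column draws from its
own RNG stream, seeded from (root seed, category, label). Adding or removing
a column consequently never shifts any other column's values, so golden
expectations survive schema evolution. Output is byte-identical for
identical (schema, configuration) pairs.

## Prolog export

Facts are ternary, `fact(Subject, predicate, Object).`, with the property
reified as the middle argument: a fixed arity keeps the export uniformly
queryable and matches triple semantics. A `per_property` mode emits
`temperature('Patients 1', 38.5).` for users who prefer one functor per
property. Dates become comparable `date(Y,M,D)` compound terms; all other
non-numeric values are single-quoted atoms with internal quotes doubled.
Predicates are normalized labels (lowercase, underscores, `p_` before a
leading digit); two labels normalizing identically abort the export, since
their facts would silently merge. Aspect pairs of complex properties export
as `property_aspect(predicate, relation, 'value').`, so a reasoner can
select, say, every left-ear measurement without enumerating property names.
The test suite parses every emitted line with an independent term grammar,
which stands in for loading the file into an interpreter.

## Problem sizes and numerical choices

The test and acceptance runs use sizes a laptop handles in seconds to a
couple of minutes: 40–100 synthetic parents for query checks, 50 randomized
schemas for the generator contract, 1,000 random values for the
encode/decode identity, exhaustive graph enumeration up to six categories
(16,807 six-node forests; all pairs checked up to four nodes, sampled pairs
above) and a 194-property schema for the scale check. Numbers encode with
up to 15 significant digits and no locale separators or scientific
notation; generated numeric samples are rounded to two decimals
(coordinates to five), comfortably inside the round-trip precision.
Degenerate inputs are first-class: empty schemas, empty categories,
all-MISSING rows, empty record sets and header-only files all have defined,
tested behavior.

## Known limitations

* One parent connection per category; deeper nesting (a child of a child)
  works by construction but has seen less testing than the core
  patient-visit shape.
* The ASK dialect covers conjunctive conditions and printouts only — no
  disjunctions, subqueries or result formatting options.
* The evaluator's `LIKE` uses glob matching; a wiki's matching rules may
  differ in case handling.
* Drilldown declarations use the modern parser-function form only.
* Aspect vocabularies default to
  `measure, exam, device, laterality, organ, time`; schemas with different
  decomposition needs must pass their own vocabulary.
* No live wiki interaction: the package writes import files and reads
  nothing back from a running site.
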