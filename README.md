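# smwbuilder

Clinical research groups usually design their data collections as
spreadsheets, while the people who have to *use* the data need a structured,
queryable database. Semantic MediaWiki (SMW) sits exactly between those two
worlds — a wiki whose pages carry typed property annotations — but setting up
an SMW database by hand means writing hundreds of interlocking property
pages, templates, entry forms and category pages. `smwbuilder` compiles all
of that from a single tab-separated schema specification, and ships the
companion machinery such a database needs day to day.

The package provides, as R functions and as a command-line tool:

* **Schema compiler** — an enriched TSV dialect (`!category`, `!group`
  directives; per-property type, range `min:max`, categorical domain
  `v1|v2|v3`, page target `->Category`, unit, note, aspect decomposition)
  compiled into MediaWiki import XML: one typed property page per property,
  one template and one PageForms form per category, category pages with
  Semantic Drilldown filter declarations, and a main page. Output is the
  standard export-0.10 page-dump dialect, byte-deterministic.
* **Data importer** — a data TSV whose columns are property labels becomes
  importable entity pages calling the category template. Entities are named
  with progressive numbers (`Patients 1`, `Patients 2`, ...); records of a
  connected category become subpages of their parent
  (`Patients 1/Visits 1`), realizing the one-to-many patient–visit relation,
  and title collisions are an error rather than a silent conflict.
* **Synthetic data generator** — fills any schema with random values that
  always satisfy the declared constraints (seeded, byte-reproducible), for
  demo sites and fixtures.
* **ASK query builder** — from a category, conditions and printouts it
  builds the inline query text, resolving property chains across categories
  automatically, including *inverse* steps rendered with a `-` prefix
  (`|?-Has Patient.Temperature`). A reference evaluator executes queries
  over record sets without a wiki.
* **Prolog fact export** — every record cell becomes a ternary
  subject–property–object fact `fact('Patients 1', temperature, 38.5).`,
  parent links become connection facts, and complex clinical properties
  ("Pure tone average of vocal gain during last control exam with
  intracochlear device on left ear") decompose into
  `property_aspect(pred, laterality, 'left').` facts for rule-based
  querying in any standard interpreter.
* **Three-valued logic** — boolean-like clinical fields support the explicit
  `NA` ("not available") value, which is distinct from a cell nobody has
  filled in yet: `NA` is stored, filtered and queried like any value, while
  MISSING never satisfies a comparator.

## Worked example

```r
library(smwbuilder)

schema_text <- paste(
  "!category\tPatients",
  "Age\tnumber\t0:120",
  "!category\tVisits\tconnection=Has Patient->Patients",
  "Temperature\tnumber\t30:45\t°C", sep = "\n")
s <- parse_schema(schema_text)
s
#> <smw_schema> "Wiki database" (lang en): 2 categories
#>   Patients: 1 properties
#>   Visits --[Has Patient]--> Patients: 1 properties

doc <- emit_site(s)            # 10 pages: main + 2x(template, form,
length(doc$pages)              # category) + Age, Temperature, Has Patient
#> [1] 10
# serialize_xml(doc) is the import XML for Special:Import

rs <- generate_records(s, gen_config(n_parents = 40, seed = 1,
                                     missing_rate = 0.1))
rs
#> <smw_recordset> 152 records (Patients: 40, Visits: 112)

# "all patients with a temperature greater than 37, and their temperatures":
q <- ask_query(s, "Patients",
               conditions = list(list(property = "Temperature",
                                      comparator = "GT", value = 37)),
               printouts = c("Age", "Temperature"))
build_ask(q, s)
#> {{#ask: [[Category:Patients]] [[-Has Patient.Temperature::>37]] |?Age |?-Has Patient.Temperature}}
```

The chain `-Has Patient` was resolved automatically: `Temperature` lives on
`Visits`, which points at `Patients` through the connection property, so the
query walks that link inversely. The reference evaluator returns the same 34
patients a brute-force filter finds:

```r
res <- evaluate_ask(q, rs)
head(res, 3)
#>       Entity  ?Age ?-Has Patient.Temperature
#> 1 Patients 1 61.96          33.48; 43; 39.16
#> 2 Patients 2 41.46               31.07; 43.7
#> 3 Patients 3 91.08       39.79; 38.13; 42.71

cat(substr(export_facts(rs), 1, 200))
#> % facts exported from schema 'Wiki database'
#> % generation seed: 1
#> fact('Patients 1', age, 61.96).
#> fact('Patients 1/Visits 1', temperature, 33.48).
#> fact('Patients 1/Visits 1', has_patient, 'Patients 1').
```

From a shell, the same workflow (see `inst/cli/smwbuilder`):

```sh
smwbuilder schema covid_schema.tsv -o site.xml
smwbuilder gen covid_schema.tsv -n 50 --seed 42 --category Samplings -o synth.tsv
smwbuilder data synth.tsv --schema covid_schema.tsv --category Samplings \
           --parent-data patients.tsv --parent-category Patients -o data.xml
smwbuilder ask covid_schema.tsv --category Samplings --where 'Temperature>37' \
           --print Temperature
smwbuilder prolog covid_schema.tsv -n 50 --seed 42 -o facts.pl
```

A COVID-like demo schema (patients with demographics, symptoms and
coordinates; samplings with temperature and swab results) ships under
`inst/extdata/covid_schema.tsv`, along with an audiology schema illustrating
aspect decomposition.

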