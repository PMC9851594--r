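#' UI string catalog for generated pages
#'
#' Generated sites can be bilingual; the boilerplate text placed on the main
#' page, templates, forms and category pages is looked up in a plain TSV
#' catalog (`key<TAB>text`) shipped under `extdata/strings_<lang>.tsv`.
#' Unknown languages fall back to English.
#'
#' @param lang Two-letter language code (`"en"` and `"it"` are shipped).
#' @return A named character vector of UI strings.
#' @export
ui_strings <- function(lang = "en") {
  path <- system.file("extdata", sprintf("strings_%s.tsv", lang),
                      package = "smwbuilder")
  if (!nzchar(path))
    path <- system.file("extdata", "strings_en.tsv", package = "smwbuilder")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(vapply(cells, `[`, character(1), 2),
                  vapply(cells, `[`, character(1), 1))
}
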