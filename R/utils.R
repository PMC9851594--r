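`%||%` <- function(a, b) if (is.null(a)) b else a

# Diagnostics are plain data frames so they print nicely and rbind cheaply.
diag_new <- function(severity = character(), line = integer(),
                     message = character()) {
  structure(
    data.frame(severity = severity, line = as.integer(line),
               message = message, stringsAsFactors = FALSE),
    class = c("smw_diagnostics", "data.frame")
  )
}

diag_add <- function(d, severity, line, message) {
  rbind(d, diag_new(severity, line, message))
}

diag_errors <- function(d) d[d$severity == "ERROR", , drop = FALSE]

#' @export
print.smw_diagnostics <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("No diagnostics.\n")
    return(invisible(x))
  }
  cat(sprintf("%s: line %d: %s", x$severity, x$line, x$message), sep = "\n")
  invisible(x)
}

# Run expr with a private RNG stream, restoring the caller's state.
with_rng <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(expr)
}

# Deterministic 31-bit string hash (FNV-1a folded); used to derive stable
# per-column RNG seeds so adding a column never perturbs the others.
str_hash31 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(enc2utf8(s))) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b %% 2^31))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% .Machine$integer.max)
}

# Byte-ordered sort, independent of the session locale.
sort_c <- function(x) sort(x, method = "radix")
order_c <- function(x) order(x, method = "radix")

# Decimal rendering used everywhere a number becomes text: no locale
# separators, no scientific notation.
num_chr <- function(v) {
  s <- vapply(v, function(x) format(x, scientific = FALSE, trim = TRUE,
                                    digits = 15),
              character(1))
  s
}
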