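# Internal helpers shared across modules.

# Stop with a condition class so callers/tests can distinguish validation
# failures from programming errors.
gcoex_error <- function(msg, class = "gcoex_error", call. = FALSE) {
  stop(structure(
    class = c(class, "gcoex_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

gcoex_warning <- function(msg) {
  warning(msg, call. = FALSE)
}

# Locale-independent lexicographic sort/order (C collation via radix).
lex_sort <- function(x) sort(x, method = "radix")
lex_order <- function(...) order(..., method = "radix")

# TRUE where a lexicographically precedes b in C collation (vectorised:
# strings are mapped to their ranks in the radix-sorted vocabulary).
lex_lt <- function(a, b) {
  vocab <- lex_sort(unique(c(a, b)))
  match(a, vocab) < match(b, vocab)
}

# Format numbers for TSV output: 6 significant digits, "" for NA.
fmt_num <- function(x) {
  out <- ifelse(is.na(x), "", sprintf("%.6g", x))
  out
}

read_text_lines <- function(path) {
  if (!file.exists(path)) {
    gcoex_error(sprintf("file not found: '%s'", path), "gcoex_io_error")
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  sub("\r$", "", lines)
}

write_text_lines <- function(lines, path) {
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    gcoex_error(sprintf("cannot open '%s' for writing: %s", path,
                        conditionMessage(e)), "gcoex_io_error")
  })
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

parse_numeric_cells <- function(x) {
  suppressWarnings(as.numeric(x))
}
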