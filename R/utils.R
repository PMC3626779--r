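# Internal helpers shared across modules.

TOOTH_LEVELS <- c("m1", "m2", "m3")
DIET_LEVELS <- c("folivorous", "carnivorous", "omnivorous", "insectivorous",
                 "frugivorous", "durophagous")

# Full-precision numeric formatting so written tables round-trip bit-for-bit.
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    formatC(v, digits = 17, format = "g")
  }, character(1))
  out
}

.write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                    ...)
}

# Attach a stage name to any error raised while evaluating `expr`, so pipeline
# failures identify the module that produced them.
.with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

.is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == round(x)

# Cheap deterministic content fingerprint for report provenance.
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  b <- utf8ToInt(s)
  h <- 5381
  for (v in b) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}
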