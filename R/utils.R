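# Internal helpers shared across modules.

# Sniff the field separator of a delimited text file from its header line:
# tab wins over comma so TSVs containing commas in labels parse correctly.
sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_delim_auto <- function(path) {
  sep <- sniff_sep(path)
  read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, comment.char = "")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Order by numeric key with a deterministic label tiebreak.
stable_order <- function(key, label) order(key, label, method = "radix")

# Deterministic expansion of one root seed into independent per-stage seeds,
# keyed by a stage tag, so adding a later stage never perturbs earlier draws.
# Values stay below 2^31 - 1 (R integer range).
stage_seed <- function(root, tag, k = 0L) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.double(root) %% 65521 * 48271 + h * 9973 + k * 7919) %%
               2147483629)
}

# TRUE/FALSE parsing tolerant of common spellings in hand-edited tables.
parse_logical <- function(x) {
  out <- rep(NA, length(x))
  lx <- tolower(trimws(as.character(x)))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out)) {
    stop("cannot parse logical value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a report list as pretty, unboxed JSON (byte-stable across reruns).
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null")
  invisible(path)
}
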