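#' @keywords internal
"_PACKAGE"

# Derive a reproducible sub-stream seed from a master seed and a string key.
# Polynomial string hash folded into [0, 2^31 - 2]; keeps set.seed() inputs
# in 32-bit integer range.
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- as.numeric(master) %% 2147483647
  for (b in utf8ToInt(as.character(key))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Stable small hash of an R object (config provenance in file headers).
object_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- TSV dialect -------------------------------------------------------------
# All writers emit a first line "# col1<TAB>col2..." plus optional extra
# comment lines; readers recover column names from that line.

write_tsv_commented <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
  if (nrow(df) > 0) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

read_tsv_commented <- function(path, colClasses = NA) {
  lines <- readLines(path)
  i <- 0L
  while (i < length(lines) && startsWith(lines[i + 1L], "#")) i <- i + 1L
  if (i == 0L) {
    stop("no '# ' header line in ", path, call. = FALSE)
  }
  header <- lines[i]  # last leading comment line carries the column names
  cols <- strsplit(sub("^# ", "", header), "\t", fixed = TRUE)[[1]]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    df <- as.data.frame(stats::setNames(replicate(length(cols), character(0),
                                                  simplify = FALSE), cols))
    return(df)
  }
  df <- utils::read.table(text = body, sep = "\t", quote = "",
                          col.names = cols, colClasses = colClasses,
                          stringsAsFactors = FALSE)
  df
}

stop_data <- function(...) stop(..., call. = FALSE)
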