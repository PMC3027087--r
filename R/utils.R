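# Internal helpers: condition classes, logging, TSV IO.

abort_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("crvnet_input_error", "crvnet_error")))
}

abort_contract <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("crvnet_contract_error", "crvnet_error")))
}

abort_pipeline <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("crvnet_pipeline_error", "crvnet_error")))
}

crv_log <- function(msg, ...) {
  message(sprintf(paste0("[crvnet] ", msg), ...))
}

write_tsv_ <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

read_tsv_ <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

# Transparent reader: gzfile() falls back to plain text for uncompressed input.
read_lines_ <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
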