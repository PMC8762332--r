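# deterministic TSV writer: fixed quoting/eol, no row names
.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

# md5 of an in-memory object via its canonical text serialization
.md5Of <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"),
             tmp)
  unname(tools::md5sum(tmp))
}
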