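`%||%` <- function(a, b) if (is.null(a)) b else a

# Write through a temp file in the same directory, then rename, so that a
# failed run never leaves a truncated output behind.
write_atomic <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(pattern = ".grmforge-", tmpdir = dir)
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop("could not move temporary file onto ", path)
  }
  invisible(path)
}

write_json_atomic <- function(x, path) {
  write_atomic(path, function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null")
  })
}

write_tsv_atomic <- function(df, path) {
  write_atomic(path, function(tmp) {
    data.table::fwrite(df, tmp, sep = "\t", quote = FALSE, na = "NA")
  })
}

usage_error <- function(...) {
  stop(structure(class = c("grmforge_usage_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
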