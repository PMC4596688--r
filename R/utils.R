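# Atomic file writing: render into a temp file in the same directory and
# rename into place, so readers never observe partial output.
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(pattern = ".nescan-", tmpdir = dir)
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

# Deterministic ordering helper used for match and region tables.
order_by <- function(df, cols) {
  do.call(order, unname(as.list(df[cols])))
}
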