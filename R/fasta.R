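#' Read protein sequences with residue-numbering offsets
#'
#' Reads a protein FASTA file. Headers may use the `name/START-END`
#' convention (e.g. `>hRio2/389-403`) to declare the reported residue
#' number of the first character; the span length must then equal the
#' sequence length. Without the suffix the numbering starts at 1.
#'
#' @param source Path to a FASTA file.
#' @return A data frame with columns `seq_id`, `residues` (upper-case
#'   string) and `numbering_offset` (reported residue number of the first
#'   character).
#' @export
read_nes_fasta <- function(source) {
  if (!file.exists(source)) stop(sprintf("FASTA file not found: %s", source))
  if (file.size(source) == 0L) stop(sprintf("FASTA file is empty: %s", source))
  set <- tryCatch(Biostrings::readAAStringSet(source),
                  error = function(e) {
                    stop(sprintf("cannot parse '%s' as FASTA: %s",
                                 source, conditionMessage(e)))
                  })
  if (length(set) == 0L) {
    stop(sprintf("no FASTA records in %s", source))
  }
  headers <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  res <- toupper(as.character(set))
  m <- regmatches(headers, regexec("^(.*)/([0-9]+)-([0-9]+)$", headers))
  seq_id <- headers
  offset <- rep(1L, length(set))
  for (i in seq_along(m)) {
    if (length(m[[i]]) == 4L) {
      from <- as.integer(m[[i]][3L])
      to <- as.integer(m[[i]][4L])
      if (to - from + 1L != nchar(res[i])) {
        stop(sprintf(
          "record '%s': header span %d-%d (%d residues) does not match sequence length %d",
          headers[i], from, to, to - from + 1L, nchar(res[i])))
      }
      seq_id[i] <- m[[i]][2L]
      offset[i] <- from
    }
    if (nchar(res[i]) == 0L) {
      stop(sprintf("record '%s': empty sequence", headers[i]))
    }
  }
  data.frame(seq_id = seq_id, residues = res, numbering_offset = offset,
             stringsAsFactors = FALSE)
}

#' Write sequence records as FASTA
#'
#' Inverse of [read_nes_fasta()]: records with `numbering_offset != 1`
#' get a `name/START-END` header.
#'
#' @param records Data frame with `seq_id`, `residues`,
#'   `numbering_offset` columns (offset defaults to 1 when absent).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_nes_fasta <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("seq_id", "residues") %in% names(records)))
  off <- if ("numbering_offset" %in% names(records)) {
    as.integer(records$numbering_offset)
  } else {
    rep(1L, nrow(records))
  }
  hdr <- ifelse(off == 1L, records$seq_id,
                sprintf("%s/%d-%d", records$seq_id, off,
                        off + nchar(records$residues) - 1L))
  set <- Biostrings::AAStringSet(records$residues)
  names(set) <- hdr
  atomic_write(path, function(tmp) {
    Biostrings::writeXStringSet(set, tmp, width = 60L)
  })
  invisible(path)
}
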