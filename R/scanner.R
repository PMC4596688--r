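#' @title Overlapping consensus-match scanning
#' @description Exhaustive start-position enumeration of gapped
#'   hydrophobic consensus matches. Every start position and every
#'   concrete spacing is tested independently, so overlapping matches are
#'   all reported (equivalent to zero-width look-ahead regular-expression
#'   capture). Coordinates are 0-based internally and 1-based inclusive
#'   reported residue numbers (via the record's `numbering_offset`) in
#'   all input and output.
#' @name scanner
NULL

# Internal: logical Phi mask for a residue string. Non-standard residues
# (X, U, B, Z, ...) are never Phi and always spacer-compatible.
phi_mask <- function(residues, phi_alphabet) {
  strsplit(residues, "", fixed = TRUE)[[1]] %in% phi_alphabet
}

#' Find all matches of one pattern in one sequence record
#'
#' @param rec A single-row data frame (or list) with `seq_id`, `residues`
#'   and `numbering_offset` fields, as returned by [read_nes_fasta()].
#' @param p An [nes_pattern()].
#' @return Raw (un-deduplicated) matches: a data frame with one row per
#'   matched span and concrete spacing, columns `seq_id`, `start`, `end`
#'   (reported residue numbers, inclusive of the first and last Phi),
#'   `orientation`, `class_name`, `phi_positions` (list column of
#'   reported Phi1..Phi4 residue numbers) and `matched_sequence`.
#'   Ordered by start, then span length. Empty data frame when nothing
#'   matches.
#' @export
find_matches <- function(rec, p) {
  stopifnot(inherits(p, "nes_pattern"))
  rec <- as.list(rec)
  res <- toupper(rec$residues)
  off <- if (is.null(rec$numbering_offset)) 1L else
    as.integer(rec$numbering_offset)
  n <- nchar(res)
  isphi <- phi_mask(res, p$phi_alphabet)
  spac <- concrete_spacings(p)
  rows <- vector("list", nrow(spac))
  for (k in seq_len(nrow(spac))) {
    gaps <- unname(spac[k, ])
    offs <- cumsum(c(0L, gaps + 1L))      # 0-based Phi offsets from start
    span <- offs[length(offs)] + 1L
    nstart <- n - span + 1L
    if (nstart < 1L) next
    ok <- rep(TRUE, nstart)
    for (o in offs) ok <- ok & isphi[seq_len(nstart) + o]
    starts <- which(ok)                    # 1-based local
    if (!length(starts)) next
    rows[[k]] <- data.frame(
      local_start = starts, span = span,
      spacing = k, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_raw_matches())
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$local_start, hits$span), , drop = FALSE]
  phis <- lapply(seq_len(nrow(hits)), function(i) {
    gaps <- unname(spac[hits$spacing[i], ])
    as.integer(hits$local_start[i] + cumsum(c(0L, gaps + 1L)) + off - 1L)
  })
  out <- data.frame(
    seq_id = rec$seq_id,
    start = as.integer(hits$local_start + off - 1L),
    end = as.integer(hits$local_start + hits$span - 1L + off - 1L),
    orientation = p$orientation,
    class_name = p$class_name,
    stringsAsFactors = FALSE)
  out$phi_positions <- phis
  out$matched_sequence <- substring(res, hits$local_start,
                                    hits$local_start + hits$span - 1L)
  out
}

empty_raw_matches <- function() {
  out <- data.frame(seq_id = character(0), start = integer(0),
                    end = integer(0), orientation = character(0),
                    class_name = character(0), stringsAsFactors = FALSE)
  out$phi_positions <- list()
  out$matched_sequence <- character(0)
  out
}

empty_matches <- function() {
  out <- data.frame(seq_id = character(0), start = integer(0),
                    end = integer(0), orientation = character(0),
                    classes = character(0), stringsAsFactors = FALSE)
  out$class_hits <- list()
  out$matched_sequence <- character(0)
  out
}

#' Scan sequence records with a pattern set
#'
#' Union of [find_matches()] over all records and patterns, optionally
#' deduplicated: raw matches sharing (seq_id, start, end, orientation)
#' are merged into a single match whose `class_hits` retains the
#' per-class Phi assignments (e.g. a 10-mer matching both 1a and 1d keeps
#' both assignments). Matches with identical span but different
#' orientation are never merged.
#'
#' @param records Data frame of sequence records ([read_nes_fasta()]).
#' @param ps An `nes_pattern_set` (or single `nes_pattern`).
#' @param dedup Merge identical spans (default `TRUE`).
#' @return Deduplicated matches: data frame with columns `seq_id`,
#'   `start`, `end`, `orientation`, `classes` (comma-joined class names),
#'   `class_hits` (list column: named list of integer Phi-position
#'   vectors) and `matched_sequence`, ordered by (seq_id, start, end,
#'   orientation). With `dedup = FALSE`, the concatenated raw matches.
#' @export
scan_sequences <- function(records, ps, dedup = TRUE) {
  if (inherits(ps, "nes_pattern")) ps <- pattern_set(list(ps), "adhoc")
  stopifnot(inherits(ps, "nes_pattern_set"), is.data.frame(records))
  raw <- list()
  for (i in seq_len(nrow(records))) {
    for (p in ps$patterns) {
      raw[[length(raw) + 1L]] <- find_matches(records[i, ], p)
    }
  }
  raw <- if (length(raw)) do.call(rbind, raw) else empty_raw_matches()
  if (!dedup) return(raw)
  dedup_matches(raw)
}

#' Merge raw matches that share an identical span and orientation
#'
#' Idempotent on already-deduplicated input (each merged match is keyed
#' by its unique span). The set of (seq_id, start, end, orientation)
#' tuples is never changed, only `class_hits` are merged.
#'
#' @param raw Raw matches from [find_matches()] /
#'   `scan_sequences(dedup = FALSE)`, or an already-merged match table.
#' @return Deduplicated match table (see [scan_sequences()]).
#' @export
dedup_matches <- function(raw) {
  stopifnot(is.data.frame(raw))
  if ("class_hits" %in% names(raw)) return(raw[order_by(
    raw, c("seq_id", "start", "end", "orientation")), , drop = FALSE])
  if (nrow(raw) == 0L) return(empty_matches())
  key <- paste(raw$seq_id, raw$start, raw$end, raw$orientation, sep = "\r")
  groups <- split(seq_len(nrow(raw)), key)
  rows <- lapply(groups, function(idx) {
    cls <- raw$class_name[idx]
    o <- order(cls)
    idx <- idx[o]
    cls <- cls[o]
    hit <- raw$phi_positions[idx]
    names(hit) <- cls
    first <- idx[1L]
    out <- data.frame(seq_id = raw$seq_id[first],
                      start = raw$start[first], end = raw$end[first],
                      orientation = raw$orientation[first],
                      classes = paste(cls, collapse = ","),
                      stringsAsFactors = FALSE)
    out$class_hits <- list(hit)
    out$matched_sequence <- raw$matched_sequence[first]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order_by(out, c("seq_id", "start", "end", "orientation")), ,
      drop = FALSE]
}

#' Annotate optional flanking Phi0 / Phi5 positions
#'
#' Plus matches gain a Phi0 annotation when a Phi-alphabet residue sits
#' three positions before Phi1 (Phi0-X-X-Phi1); minus matches gain a Phi5
#' when a Phi residue sits three positions after Phi4 (Phi4-X-X-Phi5).
#' The flank is a post-hoc annotation, never a match requirement, and the
#' match span is unchanged.
#'
#' @param matches Deduplicated match table.
#' @param records Sequence records the matches came from.
#' @param phi_alphabet Phi alphabet used for the flank test.
#' @return `matches` with added `flank_position` (reported residue number
#'   or `NA`) and `flank_residue` columns.
#' @export
annotate_flanks <- function(matches, records, phi_alphabet = PHI_DEFAULT) {
  stopifnot(is.data.frame(matches), is.data.frame(records))
  lookup <- split(records, records$seq_id)
  fp <- rep(NA_integer_, nrow(matches))
  fr <- rep(NA_character_, nrow(matches))
  for (i in seq_len(nrow(matches))) {
    recs <- lookup[[matches$seq_id[i]]]
    if (is.null(recs)) {
      stop(sprintf("match on unknown sequence '%s'", matches$seq_id[i]))
    }
    rec <- recs[1L, ]
    pos <- if (matches$orientation[i] == "plus") {
      matches$start[i] - 3L
    } else {
      matches$end[i] + 3L
    }
    local <- pos - rec$numbering_offset + 1L
    if (local >= 1L && local <= nchar(rec$residues)) {
      ch <- substring(rec$residues, local, local)
      if (ch %in% phi_alphabet) {
        fp[i] <- pos
        fr[i] <- ch
      }
    }
  }
  matches$flank_position <- fp
  matches$flank_residue <- fr
  matches
}

# ---- match table serialization ----------------------------------------

serialize_class_hits <- function(class_hits) {
  vapply(class_hits, function(h) {
    paste(vapply(names(h), function(nm) {
      paste0(nm, ":", paste(h[[nm]], collapse = ","))
    }, character(1)), collapse = ";")
  }, character(1))
}

parse_class_hits <- function(s) {
  lapply(strsplit(s, ";", fixed = TRUE), function(parts) {
    hit <- lapply(parts, function(pt) {
      kv <- strsplit(pt, ":", fixed = TRUE)[[1]]
      if (length(kv) != 2L) {
        stop(sprintf("malformed class_hits field: '%s'", pt))
      }
      as.integer(strsplit(kv[2], ",", fixed = TRUE)[[1]])
    })
    names(hit) <- vapply(parts, function(pt)
      strsplit(pt, ":", fixed = TRUE)[[1]][1], character(1))
    hit
  })
}

#' Write / read a match table as TSV
#'
#' Columns: seq_id, start, end, orientation, classes (comma-joined),
#' class_hits (`class:pos,pos,...` semicolon-joined) and
#' matched_sequence. Flank annotations are preserved when present.
#' `read_matches_tsv()` is the exact inverse of `write_matches_tsv()`.
#'
#' @param matches Deduplicated match table.
#' @param path Output (input) file path.
#' @return `path` invisibly; for the reader, the match table.
#' @export
write_matches_tsv <- function(matches, path) {
  flat <- matches
  flat$class_hits <- serialize_class_hits(matches$class_hits)
  atomic_write(path, function(tmp) {
    utils::write.table(flat, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  invisible(path)
}

#' @rdname write_matches_tsv
#' @export
read_matches_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("matches file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("seq_id", "start", "end", "orientation", "classes",
            "class_hits", "matched_sequence")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("matches TSV '%s': missing column(s) %s",
                 path, paste(miss, collapse = ", ")))
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (nrow(df)) {
    df$class_hits <- parse_class_hits(df$class_hits)
  } else {
    df$class_hits <- list()
  }
  if ("flank_position" %in% names(df)) {
    df$flank_position <- as.integer(df$flank_position)
  }
  df
}
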