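#' @title NES-region classification and minus-candidate nomination
#' @description Annotated NES regions (literature intervals on cargo
#'   proteins) are classified into four categories by the orientation of
#'   the class-1-family consensus matches they contain: `both`,
#'   `plus_only`, `minus_only` or `none`. Regions whose only
#'   class-1-family matches are minus and that are free of class-2
#'   consensus overlap are nominated as putative minus-NES candidates.
#' @name regions
NULL

REGION_CATEGORIES <- c("both", "plus_only", "minus_only", "none")

#' Read NES-region annotations from TSV
#'
#' Expects a header with columns `seq_id`, `start`, `end` and an optional
#' `region_id` (auto-generated as `region_0001`, ... when absent).
#'
#' @param source Path to the TSV file. A file with no data rows yields an
#'   empty region table.
#' @param sequences Optional sequence records; when supplied, every
#'   region must lie on a known sequence and within its numbering range.
#' @return Data frame with columns `region_id`, `seq_id`, `start`, `end`.
#' @export
read_regions <- function(source, sequences = NULL) {
  if (!file.exists(source)) stop(sprintf("regions file not found: %s", source))
  lines <- readLines(source, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) <= 1L) {
    return(data.frame(region_id = character(0), seq_id = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.delim(source, stringsAsFactors = FALSE)
  need <- c("seq_id", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("regions TSV '%s': missing column(s) %s",
                 source, paste(miss, collapse = ", ")))
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (!("region_id" %in% names(df))) {
    df$region_id <- sprintf("region_%04d", seq_len(nrow(df)))
  }
  validate_regions(df, sequences, where = source)
  df[, c("region_id", "seq_id", "start", "end")]
}

validate_regions <- function(df, sequences = NULL, where = "regions") {
  bad <- which(is.na(df$start) | is.na(df$end) | df$start > df$end)
  if (length(bad)) {
    stop(sprintf("%s: region '%s' has invalid bounds (start > end or non-numeric)",
                 where, df$region_id[bad[1]]))
  }
  dup <- df$region_id[duplicated(df$region_id)]
  if (length(dup)) {
    stop(sprintf("%s: duplicate region_id '%s'", where, dup[1]))
  }
  if (!is.null(sequences)) {
    for (i in seq_len(nrow(df))) {
      rec <- sequences[sequences$seq_id == df$seq_id[i], ]
      if (nrow(rec) == 0L) {
        stop(sprintf("%s: region '%s' refers to unknown sequence '%s'",
                     where, df$region_id[i], df$seq_id[i]))
      }
      lo <- rec$numbering_offset[1]
      hi <- lo + nchar(rec$residues[1]) - 1L
      if (df$start[i] < lo || df$end[i] > hi) {
        stop(sprintf("%s: region '%s' (%d-%d) outside sequence '%s' range %d-%d",
                     where, df$region_id[i], df$start[i], df$end[i],
                     df$seq_id[i], lo, hi))
      }
    }
  }
  invisible(df)
}

#' Write region annotations as TSV
#' @param regions Region table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_tsv <- function(regions, path) {
  atomic_write(path, function(tmp) {
    utils::write.table(
      regions[, c("seq_id", "start", "end", "region_id")], tmp,
      sep = "\t", quote = FALSE, row.names = FALSE)
  })
  invisible(path)
}

# Does match row i of `matches` satisfy the overlap policy for a region?
match_in_region <- function(m_start, m_end, r_start, r_end, policy) {
  switch(policy,
         contained = m_start >= r_start & m_end <= r_end,
         any_overlap = m_start <= r_end & m_end >= r_start,
         stop(sprintf("unknown overlap policy '%s'", policy)))
}

# Orientation-resolved class-1-family membership of each match row.
match_family <- function(matches) {
  vapply(seq_len(nrow(matches)), function(i) {
    cls <- names(matches$class_hits[[i]])
    if (any(is_class1_family(cls))) matches$orientation[i] else "other"
  }, character(1))
}

match_has_class2 <- function(matches) {
  vapply(matches$class_hits, function(h) {
    any(names(h) %in% c("2", "2-R"))
  }, logical(1))
}

#' Classify NES regions by the consensus matches they contain
#'
#' Per region, counts deduplicated class-1-family matches of each
#' orientation that satisfy the overlap policy, derives the four-way
#' category, and flags overlap with the class-2 consensus.
#'
#' @param regions Region table ([read_regions()]).
#' @param matches Deduplicated match table ([scan_sequences()]).
#' @param policy `"contained"` (match span inside the region; default) or
#'   `"any_overlap"` (spans intersect).
#' @return Data frame with columns `region_id`, `seq_id`, `start`, `end`,
#'   `category`, `n_plus_matches`, `n_minus_matches`,
#'   `overlapping_class2`; the policy is stored as an attribute.
#' @export
assign_matches <- function(regions, matches,
                           policy = c("contained", "any_overlap")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(regions), is.data.frame(matches))
  fam <- match_family(matches)
  cls2 <- match_has_class2(matches)
  out <- regions[, c("region_id", "seq_id", "start", "end")]
  n_plus <- integer(nrow(regions))
  n_minus <- integer(nrow(regions))
  has2 <- logical(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    sel <- matches$seq_id == regions$seq_id[i] &
      match_in_region(matches$start, matches$end,
                      regions$start[i], regions$end[i], policy)
    n_plus[i] <- sum(sel & fam == "plus")
    n_minus[i] <- sum(sel & fam == "minus")
    has2[i] <- any(sel & cls2)
  }
  out$category <- ifelse(n_plus > 0L & n_minus > 0L, "both",
                  ifelse(n_plus > 0L, "plus_only",
                  ifelse(n_minus > 0L, "minus_only", "none")))
  out$n_plus_matches <- n_plus
  out$n_minus_matches <- n_minus
  out$overlapping_class2 <- has2
  attr(out, "policy") <- policy
  out
}

#' Nominate putative minus-NES candidate regions
#'
#' Keeps regions classified `minus_only` whose class-2 flag is off, and
#' collects every minus-orientation class-1-family match they contain
#' (one candidate peptide per distinct match span). Reports the counts
#' at each filter stage.
#'
#' @param classifications Output of [assign_matches()].
#' @param matches The match table the classification was computed from.
#' @param sequences Optional sequence records (kept for interface
#'   symmetry; candidate peptides are taken from `matched_sequence`).
#' @param policy Overlap policy; defaults to the one recorded on
#'   `classifications`.
#' @return A list of class `minus_candidates` with elements `regions`
#'   (surviving region table), `peptides` (one row per candidate match:
#'   `seq_id`, `start`, `end`, `classes`, `sequence`) and `stage_counts`
#'   (`minus_only`, `removed_class2`, `candidate_regions`,
#'   `candidate_matches`).
#' @export
minus_candidates <- function(classifications, matches, sequences = NULL,
                             policy = NULL) {
  if (is.null(policy)) policy <- attr(classifications, "policy")
  if (is.null(policy)) policy <- "contained"
  stopifnot(is.data.frame(classifications), is.data.frame(matches))
  mo <- classifications[classifications$category == "minus_only", ,
                        drop = FALSE]
  keep <- mo[!mo$overlapping_class2, , drop = FALSE]
  fam <- match_family(matches)
  pep_rows <- list()
  for (i in seq_len(nrow(keep))) {
    sel <- which(matches$seq_id == keep$seq_id[i] & fam == "minus" &
                   match_in_region(matches$start, matches$end,
                                   keep$start[i], keep$end[i], policy))
    for (j in sel) {
      pep_rows[[paste(matches$seq_id[j], matches$start[j],
                      matches$end[j], sep = "\r")]] <-
        data.frame(seq_id = matches$seq_id[j], start = matches$start[j],
                   end = matches$end[j], classes = matches$classes[j],
                   sequence = matches$matched_sequence[j],
                   stringsAsFactors = FALSE)
    }
  }
  peptides <- if (length(pep_rows)) {
    p <- do.call(rbind, pep_rows)
    rownames(p) <- NULL
    p[order_by(p, c("seq_id", "start", "end")), , drop = FALSE]
  } else {
    data.frame(seq_id = character(0), start = integer(0),
               end = integer(0), classes = character(0),
               sequence = character(0), stringsAsFactors = FALSE)
  }
  structure(list(
    regions = keep,
    peptides = peptides,
    stage_counts = list(
      minus_only = nrow(mo),
      removed_class2 = sum(mo$overlapping_class2),
      candidate_regions = nrow(keep),
      candidate_matches = nrow(peptides))),
    class = "minus_candidates")
}

#' @export
print.minus_candidates <- function(x, ...) {
  sc <- x$stage_counts
  cat(sprintf(paste0(
    "<minus_candidates> %d minus-only region(s); %d removed by class-2 ",
    "overlap; %d candidate region(s) containing %d candidate peptide(s)\n"),
    sc$minus_only, sc$removed_class2, sc$candidate_regions,
    sc$candidate_matches))
  invisible(x)
}

#' Write candidate peptides as FASTA (plus a stage-count JSON sidecar)
#'
#' @param candidates A `minus_candidates` object.
#' @param fasta_path Output FASTA path; headers use the
#'   `seq_id/start-end` offset convention.
#' @param json_path Optional path for the stage-count JSON (default:
#'   `fasta_path` with a `.json` suffix appended).
#' @return `fasta_path`, invisibly.
#' @export
write_candidates <- function(candidates, fasta_path,
                             json_path = paste0(fasta_path, ".json")) {
  stopifnot(inherits(candidates, "minus_candidates"))
  pep <- candidates$peptides
  recs <- data.frame(seq_id = pep$seq_id, residues = pep$sequence,
                     numbering_offset = pep$start,
                     stringsAsFactors = FALSE)
  write_nes_fasta(recs, fasta_path)
  atomic_write(json_path, function(tmp) {
    jsonlite::write_json(candidates$stage_counts, tmp, auto_unbox = TRUE,
                         pretty = TRUE)
  })
  invisible(fasta_path)
}
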