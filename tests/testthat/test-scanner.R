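test_that("FASTA headers with residue-number offsets are parsed and validated", {
  recs <- fixture_records()
  hr <- recs[recs$seq_id == "hRio2", ]
  expect_identical(hr$residues, "RSFEMTEFNQALEEI")
  expect_identical(hr$numbering_offset, 389L)
  expect_identical(recs$numbering_offset[recs$seq_id == "PKI"], 1L)

  bad <- tempfile(fileext = ".fa")
  writeLines(c(">p/10-12", "ACDEF"), bad)
  expect_error(read_nes_fasta(bad), "does not match sequence length")
  writeLines(character(0), bad)
  expect_error(read_nes_fasta(bad), "empty")
})

test_that("the reversed class 1a pattern finds the printed minus NESs uniquely", {
  recs <- fixture_records(c("hRio2", "CPEB4"))
  p1aR <- reverse_pattern(default_pattern_set()$patterns[["1a"]])

  hr <- find_matches(recs[recs$seq_id == "hRio2", ], p1aR)
  expect_identical(nrow(hr), 1L)
  expect_identical(hr$phi_positions[[1]], c(391L, 393L, 396L, 400L))
  expect_identical(hr$orientation, "minus")

  cp <- find_matches(recs[recs$seq_id == "CPEB4", ], p1aR)
  expect_identical(nrow(cp), 1L)
  expect_identical(cp$phi_positions[[1]], c(381L, 383L, 386L, 390L))

  none <- find_matches(as_record(strrep("A", 12)), p1aR)
  expect_identical(nrow(none), 0L)
})

test_that("scanning the minus NES peptides with the class-1 family yields no plus match", {
  recs <- fixture_records(c("hRio2", "CPEB4"))
  fam <- expand_bidirectional(default_pattern_set())
  fam <- pattern_set(fam$patterns[grepl("^1[a-d](-R)?$",
                                        names(fam$patterns))],
                     "class1-family")
  m <- scan_sequences(recs, fam)
  expect_true(all(m$orientation == "minus"))
  expect_true(nrow(m) >= 2L)
})

test_that("identical spans from different classes merge, retaining per-class Phi sets", {
  ps <- default_bidirectional_set()
  m <- scan_sequences(as_record("LAALLAALAL"), ps)
  plus1 <- m[m$orientation == "plus" & m$start == 1L & m$end == 10L, ]
  expect_identical(nrow(plus1), 1L)
  expect_identical(plus1$classes, "1a,1d")
  expect_identical(plus1$class_hits[[1]][["1a"]], c(1L, 5L, 8L, 10L))
  expect_identical(plus1$class_hits[[1]][["1d"]], c(1L, 4L, 8L, 10L))
  # dedup of an already-merged table is the identity
  expect_identical(dedup_matches(m)$class_hits, m$class_hits)
  expect_identical(dedup_matches(m)$classes, m$classes)
})

test_that("dedup merges class hits without changing the span set", {
  set.seed(21)
  ps <- default_bidirectional_set()
  for (i in 1:20) {
    rec <- as_record(random_phi_rich_sequence(60), offset = sample(500, 1))
    raw <- scan_sequences(rec, ps, dedup = FALSE)
    merged <- scan_sequences(rec, ps, dedup = TRUE)
    key <- function(df) unique(paste(df$seq_id, df$start, df$end,
                                     df$orientation))
    expect_setequal(key(merged), key(raw))
  }
})

test_that("every reported Phi position carries a Phi-alphabet residue", {
  set.seed(31)
  ps <- default_bidirectional_set()
  for (i in 1:20) {
    seq <- random_phi_rich_sequence(80)
    m <- scan_sequences(as_record(seq), ps)
    for (j in seq_len(nrow(m))) {
      for (phis in m$class_hits[[j]]) {
        expect_true(all(strsplit(seq, "")[[1]][phis] %in% PHI))
      }
    }
  }
})

test_that("matches of a pattern mirror matches of its reversal in the reversed sequence", {
  set.seed(97)
  ps_cache <- list()
  for (i in 1:300) {
    p <- random_pattern()
    s <- random_phi_rich_sequence(sample(20:80, 1))
    n <- nchar(s)
    fwd <- find_matches(as_record(s), p)
    rev <- find_matches(as_record(reverse_string(s)), reverse_pattern(p))
    mirrored <- if (nrow(rev)) {
      sort(paste(n + 1L - rev$end, n + 1L - rev$start))
    } else character(0)
    direct <- if (nrow(fwd)) sort(paste(fwd$start, fwd$end)) else character(0)
    expect_identical(direct, mirrored)
  }
})

test_that("non-standard residues never count as Phi but pass as spacers", {
  p <- nes_pattern("1a", c(3, 2, 1))
  # Phi slots at 1,5,8,10: X in a spacer is fine, X at a Phi slot kills it
  expect_identical(nrow(find_matches(as_record("LXXXLXXLXL"), p)), 1L)
  expect_identical(nrow(find_matches(as_record("XAAALAALAL"), p)), 0L)
})

test_that("match counts on i.i.d. uniform sequences follow the closed-form rate", {
  set.seed(1234)
  n <- 20000L
  seq <- paste(sample(AA_STANDARD, n, replace = TRUE), collapse = "")
  p <- nes_pattern("3", list(c(2, 3), c(2, 3), 2))
  m <- find_matches(as_record(seq), p)
  spans <- nescan:::spacing_spans(p)
  expected <- sum(n - spans + 1) * (5 / 20)^4
  sd_bound <- sqrt(sum(n - spans + 1) * (5 / 20)^4)
  expect_lt(abs(nrow(m) - expected), 4 * sd_bound)
})

test_that("flank annotation adds Phi5 (minus) and Phi0 (plus) without moving spans", {
  recs <- fixture_records()
  ps <- default_bidirectional_set()
  hr <- annotate_flanks(scan_sequences(recs[recs$seq_id == "hRio2", ],
                                       ps), recs)
  minus <- hr[hr$orientation == "minus", ]
  expect_identical(minus$flank_position, 403L)   # Phi4 = L400, +3 = I403
  expect_identical(minus$flank_residue, "I")
  expect_identical(minus$end, 400L)              # span unchanged

  # CPEB4-R: plus class 1a core at 4-13 gains Phi0 = Ile at position 1
  cr <- recs[recs$seq_id == "CPEB4-R", ]
  mm <- annotate_flanks(scan_sequences(cr, ps), recs)
  plus1a <- mm[mm$orientation == "plus" & grepl("1a", mm$classes), ]
  expect_identical(plus1a$start, 4L)
  expect_identical(plus1a$flank_position, 1L)
  expect_identical(plus1a$flank_residue, "I")

  # no room past the sequence end: no annotation
  lone <- as_record("LALLALAALL")  # minus 1d-R match would end at the edge
  sc <- annotate_flanks(scan_sequences(lone, ps), lone)
  edge <- sc[sc$orientation == "minus" & sc$end >= nchar(lone$residues) - 2L, ]
  expect_true(all(is.na(edge$flank_position)))
})

test_that("match tables survive a TSV round-trip byte-exactly", {
  recs <- fixture_records()
  m <- annotate_flanks(scan_sequences(recs, default_bidirectional_set()),
                       recs)
  f <- tempfile(fileext = ".tsv")
  write_matches_tsv(m, f)
  back <- read_matches_tsv(f)
  rownames(m) <- NULL
  rownames(back) <- NULL
  expect_identical(back$seq_id, m$seq_id)
  expect_identical(back$start, m$start)
  expect_identical(back$class_hits, m$class_hits)
  expect_identical(back$flank_position, m$flank_position)
  # writer output is byte-stable
  f2 <- tempfile(fileext = ".tsv")
  write_matches_tsv(m, f2)
  expect_identical(readLines(f), readLines(f2))
})
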