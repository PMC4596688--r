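# Build a small deterministic protein with planted matches on a Phi-free
# background, so region categories are known by construction.
planted_protein <- function(seed = 5) {
  set.seed(seed)
  rec <- phi_free_record(400, id = "prot1")
  ps <- default_bidirectional_set()
  out <- list()
  plant <- function(rec, class, pos) {
    pl <- plant_nes(rec, class, pos, patterns = ps, spacer_policy = "keep")
    out[[length(out) + 1L]] <<- pl$truth
    pl$record
  }
  rec <- plant(rec, "1a-R", 20)    # span 20-29
  rec <- plant(rec, "1a", 60)      # span 60-69
  rec <- plant(rec, "1a-R", 100)   # span 100-109
  rec <- plant(rec, "1b-R", 130)   # span 130-140 (two minus in one region)
  rec <- plant(rec, "1a-R", 150)
  list(record = rec, truth = do.call(rbind, out))
}

test_that("region TSVs are read with validation and auto ids", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("seq_id\tstart\tend", "hRio2\t389\t403"), f)
  r <- read_regions(f)
  expect_identical(nrow(r), 1L)
  expect_identical(r$end - r$start + 1L, 15L)
  expect_identical(r$region_id, "region_0001")

  writeLines("seq_id\tstart\tend", f)
  expect_identical(nrow(read_regions(f)), 0L)

  writeLines(c("seq_id\tstart\tend", "p\t10\t5"), f)
  expect_error(read_regions(f), "invalid bounds")

  writeLines(c("seq_id\tstart\tend", "ghost\t1\t5"), f)
  expect_error(read_regions(f, sequences = fixture_records()), "ghost")
})

test_that("regions are classified by the orientation of contained matches", {
  pp <- planted_protein()
  m <- scan_sequences(pp$record, default_bidirectional_set())
  regions <- data.frame(
    region_id = c("r_minus", "r_plus", "r_both", "r_none", "r_two_minus"),
    seq_id = "prot1",
    start = c(15L, 55L, 15L, 300L, 125L),
    end = c(35L, 75L, 75L, 340L, 165L),
    stringsAsFactors = FALSE)
  cls <- assign_matches(regions, m)
  got <- stats::setNames(cls$category, cls$region_id)
  expect_identical(got[["r_minus"]], "minus_only")
  expect_identical(got[["r_plus"]], "plus_only")
  expect_identical(got[["r_both"]], "both")
  expect_identical(got[["r_none"]], "none")
  expect_identical(got[["r_two_minus"]], "minus_only")
  expect_identical(cls$n_minus_matches[cls$region_id == "r_two_minus"], 2L)
  # the categories partition the region set
  expect_identical(sum(table(cls$category)), nrow(regions))
})

test_that("a match straddling a region boundary counts under any_overlap only", {
  pp <- planted_protein()
  m <- scan_sequences(pp$record, default_bidirectional_set())
  # first plant spans 20-29; region 25-45 cuts it
  straddle <- data.frame(region_id = "cut", seq_id = "prot1",
                         start = 25L, end = 45L, stringsAsFactors = FALSE)
  contained <- assign_matches(straddle, m, policy = "contained")
  overlap <- assign_matches(straddle, m, policy = "any_overlap")
  expect_identical(contained$category, "none")
  expect_identical(overlap$category, "minus_only")
  expect_true(all(overlap$n_plus_matches >= contained$n_plus_matches))
  expect_true(all(overlap$n_minus_matches >= contained$n_minus_matches))
})

test_that("minus candidates keep class-2-free minus-only regions with all their peptides", {
  pp <- planted_protein()
  m <- scan_sequences(pp$record, default_bidirectional_set())
  regions <- data.frame(
    region_id = c("r_minus", "r_two_minus", "r_plus"),
    seq_id = "prot1",
    start = c(15L, 125L, 55L), end = c(35L, 165L, 75L),
    stringsAsFactors = FALSE)
  cls <- assign_matches(regions, m)
  cand <- minus_candidates(cls, m)
  expect_identical(cand$stage_counts$minus_only, 2L)
  expect_identical(cand$stage_counts$removed_class2, 0L)
  expect_identical(cand$stage_counts$candidate_regions, 2L)
  expect_identical(cand$stage_counts$candidate_matches, 3L)
  # one region with two distinct minus matches contributes two peptides
  expect_identical(sum(cand$peptides$start >= 125L), 2L)

  # locality: adding plus-only regions never changes the report
  more <- rbind(regions, data.frame(region_id = "r_plus2", seq_id = "prot1",
                                    start = 55L, end = 80L))
  cand2 <- minus_candidates(assign_matches(more, m), m)
  expect_identical(cand2$stage_counts$candidate_regions,
                   cand$stage_counts$candidate_regions)
  expect_identical(cand2$peptides, cand$peptides)

  # a corpus without minus matches yields an empty report
  plus_only_m <- m[m$orientation == "plus", , drop = FALSE]
  cand3 <- minus_candidates(assign_matches(regions, plus_only_m),
                            plus_only_m)
  expect_identical(cand3$stage_counts$candidate_regions, 0L)
  expect_identical(nrow(cand3$peptides), 0L)
})

test_that("planting a class-2 match inside a minus-only region flips its flag", {
  set.seed(9)
  rec <- phi_free_record(200, id = "p")
  ps <- default_bidirectional_set()
  pl <- plant_nes(rec, "1a-R", 50, patterns = ps, spacer_policy = "keep")
  region <- data.frame(region_id = "r", seq_id = "p",
                       start = 45L, end = 90L, stringsAsFactors = FALSE)
  m1 <- scan_sequences(pl$record, ps)
  c1 <- assign_matches(region, m1)
  expect_identical(c1$category, "minus_only")
  expect_false(c1$overlapping_class2)

  pl2 <- plant_nes(pl$record, "2", 75, patterns = ps,
                   spacer_policy = "keep")
  m2 <- scan_sequences(pl2$record, ps)
  c2 <- assign_matches(region, m2)
  expect_identical(c2$category, "minus_only")
  expect_true(c2$overlapping_class2)
  expect_identical(minus_candidates(c2, m2)$stage_counts$removed_class2, 1L)
})

test_that("candidate FASTA output uses offset headers and round-trips", {
  pp <- planted_protein()
  m <- scan_sequences(pp$record, default_bidirectional_set())
  regions <- data.frame(region_id = "r", seq_id = "prot1",
                        start = 15L, end = 35L, stringsAsFactors = FALSE)
  cand <- minus_candidates(assign_matches(regions, m), m)
  fa <- tempfile(fileext = ".fa")
  write_candidates(cand, fa)
  back <- read_nes_fasta(fa)
  expect_identical(back$numbering_offset, cand$peptides$start)
  expect_identical(back$residues, cand$peptides$sequence)
  counts <- jsonlite::read_json(paste0(fa, ".json"))
  expect_equal(as.integer(counts$candidate_regions), 1L)
})
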