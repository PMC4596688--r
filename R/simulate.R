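#' @title Synthetic corpora and titration series
#' @description Generates database-like corpora — background protein
#'   sequences with annotated NES regions containing planted consensus
#'   matches of chosen class and orientation — plus simulated
#'   differential-bleaching titration series, so that every pipeline
#'   stage can be exercised against known ground truth without external
#'   downloads. Region blocks are scrubbed of Phi residues before
#'   planting, which makes the intended region categories exact by
#'   construction.
#' @name synthetic
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")

# geometry of a planted region block (residues)
REGION_LEN <- 40L
REGION_BUFFER <- 15L
BLOCK_LEN <- REGION_LEN + 2L * REGION_BUFFER
# minimum gap between two plants in one region; no consensus span exceeds
# 12 residues, so a gap of 13 makes cross-plant matches impossible
PLANT_GAP <- 13L

#' Background amino-acid frequency tables
#'
#' @param name `"uniform"` (equal frequency over the 20 standard
#'   residues; the default null model) or `"swissprot"` (a SwissProt-like
#'   composition shipped with the package).
#' @return Named numeric vector over the 20 residues, summing to 1.
#' @export
aa_frequencies <- function(name = c("uniform", "swissprot")) {
  name <- match.arg(name)
  if (name == "uniform") {
    freq <- stats::setNames(rep(1 / 20, 20L), AA20)
    return(freq)
  }
  path <- system.file("extdata", "aa_frequencies_swissprot.tsv",
                      package = "nescan")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  normalize_frequencies(stats::setNames(tab$frequency, tab$residue))
}

normalize_frequencies <- function(freq) {
  if (is.character(freq) && length(freq) == 1L) freq <- aa_frequencies(freq)
  if (is.null(names(freq)) || any(nchar(names(freq)) != 1L) ||
      anyNA(freq) || any(freq < 0) || sum(freq) <= 0) {
    stop("background frequencies must be a named non-negative vector of single residues")
  }
  freq / sum(freq)
}

#' Sample i.i.d. background protein sequences
#'
#' @param n_proteins Number of sequences.
#' @param frequencies Residue frequencies: `"uniform"`, `"swissprot"` or
#'   a named numeric vector.
#' @param length_meanlog,length_sdlog Log-normal protein-length
#'   parameters.
#' @param min_length Lower bound on sequence length.
#' @param seed Optional RNG seed (set when given; callers managing their
#'   own RNG stream pass `NULL`).
#' @param prefix Sequence-id prefix.
#' @return Sequence-record data frame (see [read_nes_fasta()]).
#' @export
sample_background <- function(n_proteins, frequencies = "uniform",
                              length_meanlog = log(420),
                              length_sdlog = 0.35, min_length = 160L,
                              seed = NULL, prefix = "synprot") {
  if (!is.null(seed)) set.seed(seed)
  freq <- normalize_frequencies(frequencies)
  n_proteins <- as.integer(n_proteins)
  if (n_proteins < 0L) stop("n_proteins must be >= 0")
  if (n_proteins == 0L) {
    return(data.frame(seq_id = character(0), residues = character(0),
                      numbering_offset = integer(0),
                      stringsAsFactors = FALSE))
  }
  lens <- pmax(min_length,
               as.integer(round(stats::rlnorm(n_proteins, length_meanlog,
                                              length_sdlog))))
  res <- vapply(lens, function(L) {
    paste(sample(names(freq), L, replace = TRUE, prob = freq),
          collapse = "")
  }, character(1))
  data.frame(seq_id = sprintf("%s%04d", prefix, seq_len(n_proteins)),
             residues = res, numbering_offset = 1L,
             stringsAsFactors = FALSE)
}

# sample residues that are never Phi (used for scrubbing)
sample_non_phi <- function(n, frequencies = "uniform",
                           phi_alphabet = PHI_DEFAULT) {
  freq <- normalize_frequencies(frequencies)
  freq <- freq[!(names(freq) %in% phi_alphabet)]
  if (!length(freq) || sum(freq) <= 0) {
    stop("background frequencies leave no non-Phi residues to scrub with")
  }
  sample(names(freq), n, replace = TRUE, prob = freq / sum(freq))
}

#' Plant a consensus match into a sequence record
#'
#' Writes Phi-alphabet residues (sampled) at the Phi slots of one
#' concrete spacing of the named class, starting at `position` (reported
#' residue numbers). Under `spacer_policy = "clean"`, the spacer
#' positions and a flanking buffer are first overwritten with non-Phi
#' residues so that exactly one match of the class overlaps the planted
#' span; `"keep"` leaves the surroundings untouched (the caller has
#' already scrubbed them, or accidental extra matches are acceptable).
#'
#' @param record Single sequence record (one-row data frame or list).
#' @param class_name Pattern class to plant (e.g. `"1a"`, `"1c-R"`).
#' @param position Reported residue number of the first Phi.
#' @param patterns Pattern set the class is drawn from.
#' @param spacing Row index into [concrete_spacings()] of the class;
#'   `NULL` samples one uniformly.
#' @param spacer_policy `"clean"` or `"keep"`.
#' @param buffer Scrubbed flank width under `"clean"` (residues).
#' @param frequencies Background frequencies used for scrub residues.
#' @return List with `record` (mutated) and `truth` (one-row data frame:
#'   `seq_id`, `start`, `end`, `class_name`, `orientation`).
#' @export
plant_nes <- function(record, class_name, position,
                      patterns = default_bidirectional_set(),
                      spacing = NULL,
                      spacer_policy = c("clean", "keep"),
                      buffer = 12L, frequencies = "uniform") {
  spacer_policy <- match.arg(spacer_policy)
  record <- as.list(record)
  p <- patterns$patterns[[class_name]]
  if (is.null(p)) stop(sprintf("unknown pattern class '%s'", class_name))
  spac <- concrete_spacings(p)
  if (is.null(spacing)) {
    spacing <- if (nrow(spac) == 1L) 1L else sample.int(nrow(spac), 1L)
  }
  gaps <- unname(spac[spacing, ])
  offs <- cumsum(c(0L, gaps + 1L))
  span <- offs[length(offs)] + 1L
  off0 <- as.integer(record$numbering_offset)
  local <- position - off0 + 1L
  n <- nchar(record$residues)
  if (local < 1L || local + span - 1L > n) {
    stop(sprintf("insufficient room to plant class %s (span %d) at %d in '%s'",
                 class_name, span, position, record$seq_id))
  }
  chars <- strsplit(record$residues, "", fixed = TRUE)[[1]]
  if (spacer_policy == "clean") {
    w0 <- max(1L, local - buffer)
    w1 <- min(n, local + span - 1L + buffer)
    chars[w0:w1] <- sample_non_phi(w1 - w0 + 1L, frequencies,
                                   p$phi_alphabet)
  }
  chars[local + offs] <- sample(p$phi_alphabet, length(offs),
                                replace = TRUE)
  record$residues <- paste(chars, collapse = "")
  list(record = as.data.frame(record, stringsAsFactors = FALSE),
       truth = data.frame(seq_id = record$seq_id,
                          start = position,
                          end = position + span - 1L,
                          class_name = class_name,
                          orientation = p$orientation,
                          stringsAsFactors = FALSE))
}

#' Specify a synthetic corpus
#'
#' @param n_proteins Number of background proteins.
#' @param region_plan Data frame with columns `category` (one of `both`,
#'   `plus_only`, `minus_only`, `none`), `n` (number of regions) and
#'   `n_class2` (how many of those additionally contain a class-2
#'   consensus match; only meaningful for `minus_only`).
#' @param extra_plants Optional data frame (`class_name`, `count`) of
#'   consensus matches planted outside any region.
#' @param frequencies Background residue frequencies.
#' @param length_meanlog,length_sdlog,min_length Protein-length model.
#' @param seed RNG seed (mandatory: corpora are reproducible artefacts).
#' @return List of class `corpus_spec`.
#' @export
corpus_spec <- function(n_proteins = 246L,
                        region_plan = dbase_region_plan(),
                        extra_plants = NULL,
                        frequencies = "uniform",
                        length_meanlog = log(420), length_sdlog = 0.35,
                        min_length = 160L, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("corpus_spec: a seed is mandatory (corpora must be reproducible)")
  }
  stopifnot(is.data.frame(region_plan),
            all(c("category", "n") %in% names(region_plan)))
  if (!("n_class2" %in% names(region_plan))) region_plan$n_class2 <- 0L
  if (!all(region_plan$category %in% REGION_CATEGORIES)) {
    stop("region_plan categories must be both/plus_only/minus_only/none")
  }
  if (any(region_plan$n < 0L) || any(region_plan$n_class2 < 0L) ||
      any(region_plan$n_class2 > region_plan$n)) {
    stop("region_plan counts must satisfy 0 <= n_class2 <= n")
  }
  if (any(region_plan$n_class2 > 0L &
          region_plan$category != "minus_only")) {
    stop("class-2 contamination is only supported for minus_only regions")
  }
  if (!is.null(extra_plants)) {
    stopifnot(is.data.frame(extra_plants),
              all(c("class_name", "count") %in% names(extra_plants)))
    if (any(extra_plants$count < 0L)) stop("extra_plants counts must be >= 0")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 region_plan = region_plan, extra_plants = extra_plants,
                 frequencies = frequencies,
                 length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog,
                 min_length = as.integer(min_length),
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Database-scaled default region plan
#'
#' 290 regions over the default 246 proteins: 116 with matches of both
#' orientations, 89 plus-only, 24 minus-only (4 of them contaminated by
#' a class-2 consensus match) and 61 with no class-1-family match.
#' @return Region-plan data frame for [corpus_spec()].
#' @export
dbase_region_plan <- function() {
  data.frame(category = c("both", "plus_only", "minus_only", "none"),
             n = c(116L, 89L, 24L, 61L),
             n_class2 = c(0L, 0L, 4L, 0L),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic corpus with planted ground truth
#'
#' Realises a [corpus_spec()]: samples background proteins, carves
#' non-overlapping region blocks (each scrubbed of Phi residues in the
#' region and a 15-residue buffer), plants consensus matches according
#' to the intended category, and places any out-of-region plants in the
#' remaining sequence space. Two plants inside one region are separated
#' by a 13-residue gap, which no consensus span can bridge, so planted
#' categories are exact.
#'
#' @param spec A `corpus_spec`.
#' @return List of class `nes_corpus` with elements `sequences` (record
#'   data frame), `regions` (`region_id`, `seq_id`, `start`, `end`,
#'   `category`, `with_class2`) and `truth` (planted matches:
#'   `seq_id`, `start`, `end`, `class_name`, `orientation`,
#'   `in_region`, `region_id`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(spec$seed)
  patterns <- default_bidirectional_set()
  patterns2 <- pattern_set(c(patterns$patterns,
                             list(`2-R` = reverse_pattern(
                               patterns$patterns[["2"]]))),
                           provenance = "default")
  records <- sample_background(spec$n_proteins,
                               frequencies = spec$frequencies,
                               length_meanlog = spec$length_meanlog,
                               length_sdlog = spec$length_sdlog,
                               min_length = spec$min_length)
  # expand the plan into one row per region, shuffled
  cats <- rep(spec$region_plan$category, spec$region_plan$n)
  with2 <- unlist(mapply(function(n, k) {
    c(rep(TRUE, k), rep(FALSE, n - k))
  }, spec$region_plan$n, spec$region_plan$n_class2, SIMPLIFY = FALSE))
  if (length(cats)) {
    ord <- sample.int(length(cats))
    cats <- cats[ord]
    with2 <- with2[ord]
  }
  n_regions <- length(cats)
  # region slots: slot j of protein i starts at local 6 + (j-1)*BLOCK
  capacity <- pmax(0L, (nchar(records$residues) - 5L) %/% BLOCK_LEN)
  slots <- data.frame(protein = integer(0), slot = integer(0))
  j <- 1L
  while (nrow(slots) < n_regions) {
    avail <- which(capacity >= j)
    if (!length(avail)) {
      stop(sprintf(
        "cannot place %d regions on %d proteins (capacity %d): conflicting directives",
        n_regions, nrow(records), sum(capacity)))
    }
    slots <- rbind(slots, data.frame(protein = avail, slot = j))
    j <- j + 1L
  }
  slots <- slots[seq_len(n_regions), , drop = FALSE]

  truth <- list()
  regions <- list()
  used_slots <- integer(nrow(records))
  for (r in seq_len(n_regions)) {
    pi <- slots$protein[r]
    sl <- slots$slot[r]
    used_slots[pi] <- max(used_slots[pi], sl)
    rec <- records[pi, ]
    block0 <- 6L + (sl - 1L) * BLOCK_LEN          # local, 1-based
    rs <- block0 + REGION_BUFFER                   # region local start
    re <- rs + REGION_LEN - 1L
    chars <- strsplit(rec$residues, "", fixed = TRUE)[[1]]
    chars[block0:(block0 + BLOCK_LEN - 1L)] <-
      sample_non_phi(BLOCK_LEN, spec$frequencies)
    rec$residues <- paste(chars, collapse = "")
    region_id <- sprintf("region_%04d", r)
    plant_classes <- switch(cats[r],
      none = character(0),
      plus_only = sample(CLASS1_PLUS, 1L),
      minus_only = c(sample(CLASS1_MINUS, 1L), if (with2[r]) "2"),
      both = c(sample(CLASS1_PLUS, 1L), sample(CLASS1_MINUS, 1L)))
    pos <- rs + 2L
    for (cl in plant_classes) {
      if (pos + 12L - 1L > re) {   # 12 = widest concrete consensus span
        stop(sprintf("region '%s' cannot hold its plants", region_id))
      }
      planted <- plant_nes(rec, cl, pos, patterns = patterns2,
                           spacer_policy = "keep")
      rec <- planted$record
      tr <- planted$truth
      tr$in_region <- TRUE
      tr$region_id <- region_id
      truth[[length(truth) + 1L]] <- tr
      pos <- tr$end + 1L + PLANT_GAP
    }
    records[pi, ] <- rec
    regions[[r]] <- data.frame(region_id = region_id,
                               seq_id = rec$seq_id,
                               start = rs, end = re,
                               category = cats[r],
                               with_class2 = isTRUE(with2[r]),
                               stringsAsFactors = FALSE)
  }

  if (!is.null(spec$extra_plants)) {
    loose <- rep(spec$extra_plants$class_name, spec$extra_plants$count)
    if (length(loose)) loose <- sample(loose)
    cursor <- 6L + used_slots * BLOCK_LEN + 13L    # local start of free zone
    pi <- 1L
    for (cl in loose) {
      placed <- FALSE
      for (tries in seq_len(nrow(records))) {
        len <- nchar(records$residues[pi])
        pos <- cursor[pi]
        if (pos + 12L + 12L <= len) {              # span + buffer head-room
          planted <- plant_nes(records[pi, ], cl, pos,
                               patterns = patterns2,
                               spacer_policy = "clean",
                               frequencies = spec$frequencies)
          records[pi, ] <- planted$record
          tr <- planted$truth
          tr$in_region <- FALSE
          tr$region_id <- NA_character_
          truth[[length(truth) + 1L]] <- tr
          cursor[pi] <- cursor[pi] + 40L
          placed <- TRUE
          pi <- if (pi == nrow(records)) 1L else pi + 1L
          break
        }
        pi <- if (pi == nrow(records)) 1L else pi + 1L
      }
      if (!placed) {
        stop("cannot place all out-of-region plants: conflicting directives")
      }
    }
  }

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(seq_id = character(0), start = integer(0),
               end = integer(0), class_name = character(0),
               orientation = character(0), in_region = logical(0),
               region_id = character(0), stringsAsFactors = FALSE)
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(region_id = character(0), seq_id = character(0),
               start = integer(0), end = integer(0),
               category = character(0), with_class2 = logical(0),
               stringsAsFactors = FALSE)
  structure(list(sequences = records, regions = regions, truth = truth,
                 spec = spec),
            class = "nes_corpus")
}

#' @export
print.nes_corpus <- function(x, ...) {
  cat(sprintf("<nes_corpus> %d protein(s), %d region(s), %d planted match(es)\n",
              nrow(x$sequences), nrow(x$regions), nrow(x$truth)))
  if (nrow(x$regions)) print(table(x$regions$category))
  invisible(x)
}

#' Write a corpus to disk
#'
#' Emits `<prefix>.fasta`, `<prefix>.regions.tsv` and
#' `<prefix>.truth.json`.
#' @param corpus An `nes_corpus`.
#' @param prefix Output path prefix.
#' @return The three paths, invisibly.
#' @export
write_corpus <- function(corpus, prefix) {
  stopifnot(inherits(corpus, "nes_corpus"))
  fa <- paste0(prefix, ".fasta")
  rg <- paste0(prefix, ".regions.tsv")
  tj <- paste0(prefix, ".truth.json")
  write_nes_fasta(corpus$sequences, fa)
  write_regions_tsv(corpus$regions, rg)
  atomic_write(tj, function(tmp) {
    jsonlite::write_json(list(regions = corpus$regions,
                              planted_matches = corpus$truth,
                              seed = corpus$spec$seed),
                         tmp, pretty = TRUE, digits = NA)
  })
  invisible(c(fa, rg, tj))
}

# ---- titration simulation ---------------------------------------------

#' Standard titration designs (final post-mixing concentrations)
#'
#' Sixteen-point two-fold serial dilutions. The direct design titrates
#' receptor from 20 uM final (40 uM pre-mix) down to 0.61 nM over probe
#' at 20 nM final; the competition design titrates competitor from 50 uM
#' final (100 uM pre-mix) down to 1.5 nM over 20 nM probe and 150 nM
#' receptor.
#'
#' @param n_points Number of dilution points.
#' @param top Highest titrant concentration, molar (final).
#' @param dilution Serial dilution factor.
#' @param probe_total Probe concentration, molar (final).
#' @param receptor_total Receptor concentration for the competition
#'   design, molar (final).
#' @return Titration design data frame (descending titrant).
#' @export
direct_design <- function(n_points = 16L, top = 20e-6, dilution = 2,
                          probe_total = 20e-9) {
  titrant <- top / dilution^(seq_len(n_points) - 1L)
  data.frame(mode = "direct", probe_total = probe_total,
             receptor_total = titrant, titrant_total = titrant,
             stringsAsFactors = FALSE)
}

#' @rdname direct_design
#' @export
competition_design <- function(n_points = 16L, top = 50e-6, dilution = 2,
                               probe_total = 20e-9,
                               receptor_total = 150e-9) {
  titrant <- top / dilution^(seq_len(n_points) - 1L)
  data.frame(mode = "competition", probe_total = probe_total,
             receptor_total = receptor_total, titrant_total = titrant,
             stringsAsFactors = FALSE)
}

#' Simulate a titration series
#'
#' Signals are drawn from the equilibrium bleach-ratio model with
#' multiplicative Gaussian noise of coefficient of variation `noise_cv`.
#'
#' @param params A [binding_params()] object (ground truth).
#' @param design Titration design ([direct_design()] /
#'   [competition_design()]).
#' @param noise_cv Multiplicative noise CV (>= 0; 0 gives points exactly
#'   on the model curve).
#' @param seed Optional RNG seed.
#' @param series_id,replicate Series labels for the output table.
#' @return Titration data frame ready for [fit_titrations()].
#' @export
simulate_titration <- function(params, design = competition_design(),
                               noise_cv = 0, seed = NULL,
                               series_id = "sim", replicate = 1L) {
  stopifnot(inherits(params, "binding_params"), noise_cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  mu <- predict_signal(params, design)
  eps <- if (noise_cv > 0) stats::rnorm(length(mu), 0, noise_cv) else 0
  out <- design
  out$series_id <- series_id
  out$replicate <- as.integer(replicate)
  out$signal <- mu * (1 + eps)
  out[, c("series_id", "mode", "replicate", "probe_total",
          "receptor_total", "titrant_total", "signal")]
}
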