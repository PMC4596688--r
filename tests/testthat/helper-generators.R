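# Shared fixtures and independent oracles, built in code.

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
PHI <- c("L", "V", "I", "F", "M")
NON_PHI <- setdiff(AA_STANDARD, PHI)

fixture_fasta <- function() {
  system.file("extdata", "nes_peptides.fasta", package = "nescan")
}

fixture_records <- function(ids = NULL) {
  recs <- read_nes_fasta(fixture_fasta())
  if (!is.null(ids)) recs <- recs[recs$seq_id %in% ids, , drop = FALSE]
  recs
}

# A random legal pattern: 2-5 Phi slots, gap sets drawn from 1..4.
random_pattern <- function(name = "rnd") {
  n_gaps <- sample(1:4, 1)
  spacers <- lapply(seq_len(n_gaps), function(i) {
    sample(1:4, sample(1:2, 1))
  })
  nes_pattern(name, spacers)
}

# Phi-rich random sequence so that matches actually occur.
random_phi_rich_sequence <- function(len, phi_prob = 0.45) {
  paste(ifelse(runif(len) < phi_prob,
               sample(PHI, len, replace = TRUE),
               sample(NON_PHI, len, replace = TRUE)),
        collapse = "")
}

as_record <- function(seq, id = "seq", offset = 1L) {
  data.frame(seq_id = id, residues = seq, numbering_offset = offset,
             stringsAsFactors = FALSE)
}

# Record with no Phi residues at all (clean planting substrate).
phi_free_record <- function(len, id = "bg", offset = 1L) {
  as_record(paste(sample(NON_PHI, len, replace = TRUE), collapse = ""),
            id, offset)
}

reverse_string <- function(s) {
  paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
}

# Background frequencies with all Phi mass removed: corpora built with
# these contain no accidental consensus matches.
phi_free_frequencies <- function() {
  stats::setNames(rep(1 / length(NON_PHI), length(NON_PHI)), NON_PHI)
}

# Independent equilibrium oracle: bisection on free receptor for the
# coupled three-species mass balances (never calls package internals).
oracle_free_receptor <- function(Rt, Pt, Ct, Kp, Kc, iters = 200) {
  g <- function(R) R * (1 + Pt / (Kp + R) + Ct / (Kc + R)) - Rt
  lo <- 0
  hi <- Rt
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Closed-form 2x2 chi-square (uncorrected), the N(ad-bc)^2 / products form.
oracle_chisq_closed_form <- function(tab) {
  tab <- matrix(as.numeric(tab), 2)
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# Direct evaluation of sum((O-E)^2 / E) from marginals.
oracle_chisq_oe <- function(tab) {
  tab <- matrix(as.numeric(tab), 2)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}
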