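---
title: "Bidirectional NES consensus scanning and CRM1 affinity estimation"
author: "nescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional NES consensus scanning and CRM1 affinity estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nescan)
```

# The consensus model

A nuclear export signal (NES) is modelled here as a chain of four core
hydrophobic slots Φ1–Φ4 (alphabet Leu, Val, Ile, Phe, Met) separated by
spacers of arbitrary residues. A consensus *class* fixes the allowed
spacer lengths between consecutive Φ slots. The six plus-orientation
classes use spacer counts

| class | spacers | span (residues) |
|-------|-----------------|------|
| 1a | 3, 2, 1 | 10 |
| 1b | 2, 2, 1 | 9 |
| 1c | 3, 3, 1 | 11 |
| 1d | 2, 3, 1 | 10 |
| 2  | 1, 2, 1 | 8 |
| 3  | {2,3}, {2,3}, 2 | 10–12 |

Because NES peptides can dock into the CRM1 groove in either
polypeptide direction, each class has a reversed counterpart: reversing
the spacer order, flipping the orientation label and toggling a `-R`
suffix. Reversal is an involution, and a class is *symmetric* when its
set of concrete spacings is invariant under reversal. Class 2 (1,2,1)
is symmetric; classes 1a–1d are not, so reversing them yields four
genuinely new minus classes 1a-R–1d-R and an eight-pattern
class-1 family for bidirectional scanning. Class 3 deserves a note:
with its variable spacers {2,3},{2,3},{2} the reversed spacing set
({2},{2,3},{2,3}) differs, so under this package's definition class 3
is *not* symmetric, although its fixed central form (2,3,2) would be.
We keep the variable-spacer form and treat class 3, like class 2, as a
plus pattern outside the class-1 family; patterns are config-driven
(`load_pattern_config()`) so either convention can be swapped in.

A second documented choice concerns the spacer counts themselves. The
residue-level Φ assignments of the worked minus examples (hRio2
F391·x·M393·xx·F396·xxx·L400, CPEB4 F381·x·M383·xx·L386·xxx·L390) fix
the minus class 1a-R gaps as 1, 2, 3 — i.e. plus class 1a = 3, 2, 1.
Printed one-line pattern strings elsewhere transpose the inner spacers;
the residue-level assignments win here because they are anchored to
concrete, numbered residues.

The Φ0 (plus) / Φ5 (minus) flank — a fifth hydrophobic three positions
before Φ1, respectively after Φ4 — is recorded by `annotate_flanks()`
as an optional annotation, never as a match requirement: the scanner's
match count semantics are those of a four-slot core.

# Scanning semantics

`find_matches()` enumerates every start position and every concrete
spacing of a pattern and reports a match whenever all Φ slots hold
Φ-alphabet residues. This exhaustive enumeration is equivalent to
regular-expression capture with zero-width look-ahead: overlapping
matches are all reported, with no greedy-match semantics. Non-standard
residues (X, U, B, Z) never satisfy a Φ slot but are acceptable
spacers.

Coordinates are 0-based half-open internally; every interface reports
1-based inclusive residue numbers through the record's
`numbering_offset`, which FASTA headers declare with the
`name/start-end` convention (e.g. `>hRio2/389-403`).

Duplicate spans are merged by the key (sequence, start, end,
orientation). Per-class Φ assignments are all retained, because two
classes can match the same span with different Φ2 (1a vs 1d on a
10-mer). Matches of opposite orientation on the same span are never
merged. The central correctness property — matches of a pattern map
exactly, under string reversal, onto matches of the reversed pattern in
the reversed sequence — is enforced by property tests over a thousand
random sequence/pattern pairs.

# Region classification and candidate nomination

Annotated NES regions are classified by the class-1-family matches they
contain into `both`, `plus_only`, `minus_only` or `none`; a separate
flag records overlap with the (symmetric) class-2 consensus. Because
"contains" is ambiguous for a match hanging over a region edge, both a
`contained` policy (match span inside the region; the default — a
region *contains* sequences that match) and an `any_overlap` policy are
exposed. Minus-NES candidates are the `minus_only` regions whose
class-2 flag is off; the report keeps the counts at every filter stage
(minus-only before filtering, removed by class-2 overlap, surviving
regions, surviving match peptides) and emits one candidate peptide per
distinct minus-match span.

For the enrichment question — are plus matches over-represented inside
annotated regions? — the 2×2 table of orientation × region membership
counts each deduplicated class-1-family match once, even when it lies
in several overlapping regions. The literature counts behind the
corresponding published test could be reconstructed either per match or
per region; this package counts matches and reports the table alongside
the statistic so the unit is explicit. The chi-square statistic is
computed from first principles (expected counts from marginals,
optional Yates correction capped at |O−E|) and is verified in the test
suite against the closed 2×2 form N(ad−bc)²/((a+b)(c+d)(a+c)(b+d)) and
against `stats::chisq.test` to 1e-12; the p-value uses the χ²(1) upper
tail. Both correction modes are always reported, Yates first, matching
the long-standing default of the R test the field uses.

# The binding model

The differential-bleaching assay observes a bleach ratio: mean
fluorescence in a late window of the bleaching phase divided by the
mean just after bleaching begins (`bleach_ratio()`). Free and
CRM1-bound probe bleach at different specific rates, so the ratio is a
two-state observable, linear in the bound-probe fraction *f*:

    signal = s_free + (s_bound − s_free) · f

**Direct titration.** Receptor titrated into probe; *f* is the exact
1:1 depletion solution `f = ((C+P+K) − sqrt((C+P+K)² − 4CP))/(2P)`,
evaluated in the rationalised form `2C/(S + sqrt(S² − 4CP))` to stay
accurate at receptor excess.

**Competition titration.** Unlabelled competitor titrated into probe
plus receptor. Free receptor R solves the three-species mass-balance
cubic `R (1 + P_t/(K_p+R) + C_t/(K_c+R)) = R_t`; the unique root in
[0, R_t] is taken from the trigonometric closed form of the cubic,
polished by Newton steps and guarded by a bisection fallback. Returned
solutions satisfy receptor conservation to better than 1e-6 relative or
an error is raised with the inputs echoed. At zero competitor the
routine degenerates exactly to the direct quadratic. RanGTP is assumed
saturating and is not modelled.

**Concentrations** are molar and *final* (post 1:1 mixing): the default
direct design titrates receptor 20 µM → 0.61 nM (16 two-fold steps)
over 20 nM probe; the competition design titrates competitor
50 µM → 1.5 nM over 20 nM probe and 150 nM receptor. These follow from
halving the published pre-mix values (40 µM / 100 µM tops, 40 nM probe,
300 nM receptor).

**Fitting.** The published description of the original fitting software
is deferred to a manuscript in preparation, so this package fixes its
own defaults and documents them: unweighted least squares on bleach
ratios over all points jointly; signal endpoints shared across series
(per-series endpoints selectable via `share_endpoints = FALSE`);
dissociation constants log-parameterised; multistart Nelder–Mead over
the constants, seeded from a coarse log-grid profile, with the
endpoints solved exactly by linear least squares at every step.
Whether the original software fitted raw time traces or window ratios,
and whether replicates were averaged, is unknown; we fit window ratios
and treat replicate series as additional points.

**Confidence intervals.** 68.3% intervals come from error-surface
projection: the named constant is scanned on a log grid, all other
parameters re-optimised at each value, and the interval is
{θ : SSR(θ) ≤ SSR_min (1 + F(1, dof) crit / dof)} (a Bevington-style
single-parameter F projection), with endpoints refined by bisection to
three significant digits. A side that never crosses the threshold
within the scan range (six decades) is reported `NA` and flagged open.
On an exactly quadratic error surface this reproduces the closed-form
half-width √(SSR_min·F_crit/(dof·curvature)), which the test suite
asserts.

# The synthetic-data module

`generate_corpus()` emulates the structure of a curated NES cargo
compilation: by default 246 proteins carrying 290 annotated NES
regions, partitioned 116 `both` / 89 `plus_only` / 24 `minus_only`
(4 with class-2 contamination) / 61 `none` — the shape of the published
region classification, used here purely as a realistic layout.
Background sequences are i.i.d. draws, uniform over the 20 residues by
default (a deliberately simple null for which the closed-form match
rate per start site, Σ_spacings (5/20)⁴, is testable); a SwissProt-like
frequency table ships as an option. Protein lengths are log-normal
(median 420 aa, σ_log 0.35, floor 160 aa), ordinary for a eukaryotic
proteome.

Planting is engineered so intended categories are *exact*: each region
sits in a 70-residue block scrubbed of Φ residues (region of 40 plus
15-residue buffers), plants write sampled Φ residues onto one concrete
spacing of their class, and two plants within a region are separated by
a 13-residue gap — wider than any consensus span (max 12), so no match
can combine Φs from two plants. Out-of-region plants are scrubbed
locally the same way (`spacer_policy = "clean"`). In consequence
scanner recall of planted matches is exactly 1 and the pipeline's
category partition must equal the plan, which the tests assert over
random corpora.

What the generator does **not** emulate: real proteomes are not i.i.d.
(hydrophobic cores, helices and disorder cluster Φ residues);
literature NES regions overlap and their boundaries are noisy; and real
consensus matches are not surrounded by Φ-free buffers. Passing the
planted-category tests therefore demonstrates the correctness of the
scanning/classification machinery, not the real-data prevalence of
minus NESs; the published real-corpus counts depend on the external
database and are deliberately not reproduction targets.

`simulate_titration()` draws signals from the equilibrium model with
multiplicative Gaussian noise (default CV 2%, the scale suggested by
the published replicate scatter), with bleach-ratio endpoints
s_free = 0.85, s_bound = 0.55 (bound probe bleaches faster, i.e. a
lower late/early ratio, matching the reported direction of the effect)
and a probe dissociation constant of 50 nM, a typical value for a
strong NES probe.

# Numerical choices and problem sizes

* Equilibrium roots: closed-form cubic + Newton polish, residual gate
  1e-9 with bisection fallback (80 halvings); acceptance gate 1e-6
  relative on receptor conservation.
* Optimiser: Nelder–Mead reltol 1e-13 with one restart; profile
  re-optimisation by golden-section over ±4 decades around the
  estimate.
* CI bisection stops at a relative bracket width of 1e-4 (three
  significant digits).
* Chi-square requires all four marginals positive, erring on degenerate
  tables; the Yates reduction is capped so |O−E| never goes negative.
* Ties in the scanner are ordered deterministically (start, span;
  sequence, start, end, orientation after dedup).

The test suite exercises the reversal-duality property on 1300 random
sequence/pattern pairs, chi-square oracle equivalence on 1200 random
tables, the equilibrium solver on 1.2 × 10⁴ random draws, parameter
recovery on 20 seeded triplicate datasets at 2% noise, and CI coverage
on 200 simulated datasets — sizes chosen to make the Monte-Carlo
assertions statistically meaningful (binomial 4σ bounds; a ±10-point
band around the nominal 68.3% coverage) while the whole suite stays
comfortably reproducible on a laptop.

# Known limitations

* The scanner matches declared consensus patterns only; it is not an
  NES predictor — no position-specific scoring, helicity, disorder or
  solvent-accessibility features, and most consensus matches in real
  proteins are not functional NESs.
* Class 2/3 minus behaviour is represented only through pattern
  symmetry; whether true class 2/3 peptides bind in the minus direction
  is an open experimental question, and the candidate filter uses the
  plus class 2 pattern (moot under symmetry).
* The binding model is strictly 1:1 and mutually exclusive; no
  cooperative or 2:1 schemes, no photobleaching kinetics, no instrument
  file parsing.
* Unweighted least squares on ratios slightly mis-weights
  multiplicative noise; at the 2% level this is negligible (the
  coverage experiment stays within its band), but strongly
  heteroscedastic data would warrant weights.
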