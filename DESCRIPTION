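Package: nescan
Title: Bidirectional Nuclear Export Signal Consensus Scanning and
    CRM1-NES Affinity Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for working with the bidirectional (plus and minus
    orientation) nuclear export signal (NES) consensus recognised by the
    exportin CRM1. Represents gapped hydrophobic consensus classes
    (1a-1d, 2, 3) and their reversed minus counterparts (1a-R to 1d-R),
    scans protein sequences for all (including overlapping) consensus
    matches with per-class hydrophobic position assignments, classifies
    annotated NES regions by the orientation of the matches they
    contain, nominates putative minus-NES candidates, and tests plus
    versus minus enrichment within NES regions by chi-square. Also
    models the competition differential-bleaching assay used to measure
    CRM1-NES dissociation constants: exact two- and three-species
    binding equilibria, joint least-squares fitting of direct and
    competition titrations, and 68.3% error-surface (F-statistic)
    confidence intervals. A synthetic-data module generates corpora
    with planted consensus matches and simulated titration series so
    the whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
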