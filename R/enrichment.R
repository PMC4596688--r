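#' @title Plus/minus enrichment within NES regions
#' @description Builds the 2x2 contingency table of class-1-family
#'   consensus matches (rows: plus/minus orientation; columns: inside /
#'   outside annotated NES regions) and tests orientation enrichment
#'   with the Pearson chi-square statistic (df = 1), optionally with the
#'   Yates continuity correction.
#' @name enrichment
NULL

#' Build the plus/minus x in/out-of-region contingency table
#'
#' Only deduplicated class-1-family matches enter the table. A match is
#' "in region" when it satisfies the overlap policy for at least one
#' region; each match is counted once even if inside several regions.
#'
#' @param matches Deduplicated match table.
#' @param regions Region table on the same proteins.
#' @param policy Overlap policy, `"contained"` or `"any_overlap"`.
#' @return 2x2 integer matrix with rows `plus`, `minus` and columns
#'   `in_region`, `out_region`.
#' @export
build_contingency <- function(matches, regions,
                              policy = c("contained", "any_overlap")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(matches), is.data.frame(regions))
  if (nrow(matches) == 0L) {
    stop("no matches supplied: cannot build a contingency table")
  }
  fam <- match_family(matches)
  famsel <- fam %in% c("plus", "minus")
  inreg <- logical(nrow(matches))
  for (i in seq_len(nrow(regions))) {
    inreg <- inreg | (matches$seq_id == regions$seq_id[i] &
                        match_in_region(matches$start, matches$end,
                                        regions$start[i], regions$end[i],
                                        policy))
  }
  tab <- matrix(c(
    sum(famsel & fam == "plus" & inreg),
    sum(famsel & fam == "plus" & !inreg),
    sum(famsel & fam == "minus" & inreg),
    sum(famsel & fam == "minus" & !inreg)),
    nrow = 2L, byrow = TRUE,
    dimnames = list(c("plus", "minus"), c("in_region", "out_region")))
  storage.mode(tab) <- "integer"
  tab
}

#' Pearson chi-square test on a 2x2 table
#'
#' Computes the statistic from first principles: expected counts from the
#' marginals, then `sum((|O - E| - c)^2 / E)` with `c = min(0.5, |O - E|)`
#' under the Yates continuity correction and `c = 0` otherwise. The
#' p-value is the upper tail of the chi-square distribution with one
#' degree of freedom.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param yates Apply the continuity correction (default `TRUE`, the
#'   conventional default for 2x2 tables).
#' @return Object of class `nes_chisq`: list with `table`, `expected`,
#'   `statistic`, `df` (= 1), `p_value`, `yates`.
#' @export
chi_square <- function(table, yates = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("chi_square needs a 2x2 table")
  if (any(table < 0) || anyNA(table)) {
    stop("chi_square: counts must be non-negative and finite")
  }
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    stop("degenerate contingency table: a row or column marginal is zero")
  }
  n <- sum(table)
  expected <- outer(rs, cs) / n
  dev <- abs(table - expected)
  if (yates) dev <- dev - pmin(0.5, dev)
  statistic <- sum(dev^2 / expected)
  structure(list(table = table, expected = expected,
                 statistic = statistic, df = 1L,
                 p_value = stats::pchisq(statistic, df = 1L,
                                         lower.tail = FALSE),
                 yates = yates),
            class = "nes_chisq")
}

#' @export
print.nes_chisq <- function(x, ...) {
  cat(sprintf("<nes_chisq> X-squared = %.6g, df = 1, p = %s%s\n",
              x$statistic, format(x$p_value, digits = 4,
                                  scientific = TRUE),
              if (x$yates) " (Yates-corrected)" else ""))
  print(x$table)
  invisible(x)
}

#' Orientation-enrichment test on scanned matches
#'
#' Convenience wrapper: builds the contingency table and runs the
#' chi-square test in both correction modes.
#'
#' @inheritParams build_contingency
#' @return List with `table`, `yates` and `uncorrected` (`nes_chisq`
#'   objects) and `policy`.
#' @export
enrichment_test <- function(matches, regions,
                            policy = c("contained", "any_overlap")) {
  policy <- match.arg(policy)
  tab <- build_contingency(matches, regions, policy)
  list(table = tab,
       yates = chi_square(tab, yates = TRUE),
       uncorrected = chi_square(tab, yates = FALSE),
       policy = policy)
}

#' Serialize an enrichment result as JSON
#' @param result Output of [enrichment_test()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_enrichment_json <- function(result, path) {
  payload <- list(
    table = list(rows = rownames(result$table),
                 cols = colnames(result$table),
                 counts = unname(apply(result$table, 1L, as.list))),
    policy = result$policy,
    yates = list(statistic = result$yates$statistic, df = 1,
                 p_value = format(result$yates$p_value, digits = 6,
                                  scientific = TRUE)),
    uncorrected = list(statistic = result$uncorrected$statistic, df = 1,
                       p_value = format(result$uncorrected$p_value,
                                        digits = 6, scientific = TRUE)))
  atomic_write(path, function(tmp) {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  })
  invisible(path)
}
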