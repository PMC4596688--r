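#' @title NES consensus patterns
#' @description Gapped hydrophobic consensus classes and their reversal
#'   algebra. A pattern is a chain of Phi slots (hydrophobic positions,
#'   alphabet L/V/I/F/M by default) separated by spacers of any residue;
#'   each spacer carries a set of allowed gap lengths. Minus-orientation
#'   classes are obtained by reversing the spacer order and carry a "-R"
#'   suffix.
#' @name patterns
NULL

# Default Phi alphabet: Leu, Val, Ile, Phe, Met.
PHI_DEFAULT <- c("L", "V", "I", "F", "M")

CLASS1_PLUS <- c("1a", "1b", "1c", "1d")
CLASS1_MINUS <- paste0(CLASS1_PLUS, "-R")

#' Construct an NES consensus pattern
#'
#' @param class_name Label such as `"1a"`, `"1a-R"`, `"2"`, `"3"`.
#' @param spacers Ordered spacer specification: a list with one element per
#'   inter-Phi gap, each an integer vector of allowed gap lengths (all
#'   >= 1). A plain integer vector is taken as fixed gaps. The number of
#'   Phi slots is `length(spacers) + 1`.
#' @param orientation `"plus"` or `"minus"`. When `NULL`, inferred from the
#'   class name: names ending in `"-R"` are minus, others plus.
#' @param phi_alphabet Characters accepted at Phi slots.
#' @return An object of class `nes_pattern`.
#' @examples
#' nes_pattern("1a", c(3, 2, 1))
#' nes_pattern("3", list(c(2, 3), c(2, 3), 2))
#' @export
nes_pattern <- function(class_name, spacers, orientation = NULL,
                        phi_alphabet = PHI_DEFAULT) {
  if (!is.character(class_name) || length(class_name) != 1L ||
      is.na(class_name) || !nzchar(class_name)) {
    stop("pattern class_name must be a single non-empty string")
  }
  if (!is.list(spacers)) spacers <- as.list(spacers)
  if (length(spacers) < 1L) {
    stop(sprintf("class '%s': need at least one spacer (n_phi >= 2)",
                 class_name))
  }
  spacers <- lapply(spacers, function(s) {
    s <- suppressWarnings(as.integer(s))
    sort(unique(s))
  })
  for (s in spacers) {
    if (length(s) == 0L || anyNA(s) || any(s < 1L)) {
      stop(sprintf(
        "class '%s': malformed spacer spec (each gap set must be non-empty integers >= 1)",
        class_name))
    }
  }
  phi_alphabet <- unique(toupper(as.character(phi_alphabet)))
  if (length(phi_alphabet) == 0L || anyNA(phi_alphabet) ||
      any(nchar(phi_alphabet) != 1L)) {
    stop(sprintf("class '%s': Phi alphabet must be a non-empty set of single letters",
                 class_name))
  }
  if (is.null(orientation)) {
    orientation <- if (grepl("-R$", class_name)) "minus" else "plus"
  }
  orientation <- match.arg(orientation, c("plus", "minus"))
  structure(
    list(class_name = class_name,
         orientation = orientation,
         phi_alphabet = phi_alphabet,
         spacer_specs = spacers,
         n_phi = length(spacers) + 1L),
    class = "nes_pattern")
}

#' @export
print.nes_pattern <- function(x, ...) {
  gaps <- vapply(x$spacer_specs, function(s) {
    if (length(s) == 1L) as.character(s) else
      paste0("{", paste(s, collapse = ","), "}")
  }, character(1))
  cat(sprintf("<nes_pattern> class %s (%s): Phi %s Phi; alphabet {%s}\n",
              x$class_name, x$orientation,
              paste0("X", gaps, " ", collapse = ""),
              paste(x$phi_alphabet, collapse = "")))
  invisible(x)
}

#' Bundle patterns into a validated set
#'
#' @param patterns List of [nes_pattern()] objects.
#' @param provenance Free-text provenance (config path or `"default"`).
#' @return Object of class `nes_pattern_set`; patterns are kept in a list
#'   named by class.
#' @export
pattern_set <- function(patterns, provenance = "manual") {
  if (inherits(patterns, "nes_pattern")) patterns <- list(patterns)
  ok <- vapply(patterns, inherits, logical(1), what = "nes_pattern")
  if (!all(ok)) stop("pattern_set: all elements must be nes_pattern objects")
  nm <- vapply(patterns, `[[`, character(1), "class_name")
  dup <- nm[duplicated(nm)]
  if (length(dup)) {
    stop(sprintf("duplicate pattern class name(s): %s",
                 paste(unique(dup), collapse = ", ")))
  }
  names(patterns) <- nm
  structure(list(patterns = patterns, provenance = provenance),
            class = "nes_pattern_set")
}

#' @export
print.nes_pattern_set <- function(x, ...) {
  cat(sprintf("<nes_pattern_set> %d pattern(s) [%s]\n",
              length(x$patterns), x$provenance))
  for (p in x$patterns) print(p)
  invisible(x)
}

#' @export
length.nes_pattern_set <- function(x) length(x$patterns)

#' Built-in plus-orientation consensus classes
#'
#' The six canonical plus classes. Spacer counts between consecutive Phi
#' positions: 1a = 3,2,1; 1b = 2,2,1; 1c = 3,3,1; 1d = 2,3,1; 2 = 1,2,1;
#' 3 = {2,3},{2,3},2.
#'
#' @return An `nes_pattern_set` of the six plus classes.
#' @export
default_pattern_set <- function() {
  pattern_set(list(
    nes_pattern("1a", c(3L, 2L, 1L)),
    nes_pattern("1b", c(2L, 2L, 1L)),
    nes_pattern("1c", c(3L, 3L, 1L)),
    nes_pattern("1d", c(2L, 3L, 1L)),
    nes_pattern("2",  c(1L, 2L, 1L)),
    nes_pattern("3",  list(c(2L, 3L), c(2L, 3L), 2L))
  ), provenance = "default")
}

#' Load a pattern set from a YAML config (or the built-in default)
#'
#' The config is a YAML document with a top-level `patterns` list; each
#' entry has `class_name`, `spacers` (list of int or list of int vectors),
#' and optional `phi_alphabet` / `orientation`. See
#' `system.file("extdata", "patterns_default.yaml", package = "nescan")`.
#'
#' @param config_source Path to a YAML file, or `NULL` for the default set.
#' @return An `nes_pattern_set`.
#' @export
load_pattern_config <- function(config_source = NULL) {
  if (is.null(config_source)) return(default_pattern_set())
  if (!file.exists(config_source)) {
    stop(sprintf("pattern config not found: %s", config_source))
  }
  doc <- yaml::read_yaml(config_source)
  entries <- if (!is.null(doc$patterns)) doc$patterns else doc
  if (!is.list(entries) || length(entries) == 0L) {
    stop(sprintf("pattern config '%s' defines no patterns", config_source))
  }
  pats <- lapply(entries, function(e) {
    if (is.null(e$class_name)) {
      stop(sprintf("pattern config '%s': entry without class_name",
                   config_source))
    }
    nes_pattern(
      class_name = e$class_name,
      spacers = e$spacers,
      orientation = e$orientation,
      phi_alphabet = if (is.null(e$phi_alphabet)) PHI_DEFAULT else
        unlist(e$phi_alphabet))
  })
  pattern_set(pats, provenance = config_source)
}

#' Reverse a consensus pattern
#'
#' Reverses the spacer order, flips the orientation, and toggles the "-R"
#' class-name suffix. Reversal is an involution:
#' `reverse_pattern(reverse_pattern(p))` equals `p`.
#'
#' @param p An `nes_pattern`.
#' @return The reversed `nes_pattern`.
#' @examples
#' reverse_pattern(nes_pattern("1a", c(3, 2, 1)))  # 1a-R, gaps 1,2,3
#' @export
reverse_pattern <- function(p) {
  stopifnot(inherits(p, "nes_pattern"))
  new_name <- if (grepl("-R$", p$class_name)) {
    sub("-R$", "", p$class_name)
  } else {
    paste0(p$class_name, "-R")
  }
  nes_pattern(new_name, rev(p$spacer_specs),
              orientation = if (p$orientation == "plus") "minus" else "plus",
              phi_alphabet = p$phi_alphabet)
}

#' Expand a pattern set with reversed (minus) classes
#'
#' @param ps An `nes_pattern_set`.
#' @param classes_to_reverse Class names to reverse; default the class-1
#'   family `1a`-`1d`, which together with their reversals gives the eight
#'   class-1-family patterns used for bidirectional scanning.
#' @return The expanded `nes_pattern_set`.
#' @export
expand_bidirectional <- function(ps, classes_to_reverse = CLASS1_PLUS) {
  stopifnot(inherits(ps, "nes_pattern_set"))
  classes_to_reverse <- as.character(classes_to_reverse)
  unknown <- setdiff(classes_to_reverse, names(ps$patterns))
  if (length(unknown)) {
    stop(sprintf("unknown class label(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  extra <- lapply(ps$patterns[classes_to_reverse], reverse_pattern)
  pattern_set(c(ps$patterns, extra), provenance = ps$provenance)
}

#' Default bidirectional pattern set
#'
#' The six plus classes plus the reversed class-1 family (1a-R to 1d-R):
#' ten patterns, eight of them class-1-family.
#' @return An `nes_pattern_set` of 10 patterns.
#' @export
default_bidirectional_set <- function() {
  expand_bidirectional(default_pattern_set())
}

#' Enumerate the concrete (fixed-gap) spacings of a pattern
#'
#' Cartesian expansion of the spacer sets, in lexicographic order.
#'
#' @param p An `nes_pattern`.
#' @return Integer matrix, one row per concrete gap tuple, one column per
#'   inter-Phi gap. The matched span of a tuple is
#'   `n_phi + sum(gaps)` residues.
#' @export
concrete_spacings <- function(p) {
  stopifnot(inherits(p, "nes_pattern"))
  g <- do.call(expand.grid, rev(p$spacer_specs))
  m <- as.matrix(g)[, rev(seq_len(ncol(g))), drop = FALSE]
  dimnames(m) <- list(NULL, paste0("gap", seq_len(ncol(m))))
  storage.mode(m) <- "integer"
  m
}

#' Is a pattern symmetric under reversal?
#'
#' A pattern is symmetric when its set of concrete spacings equals that of
#' its reversal (e.g. class 2 with gaps 1,2,1). Symmetric patterns match
#' the same spans in both orientations.
#'
#' @param p An `nes_pattern`.
#' @return Logical scalar.
#' @export
is_symmetric <- function(p) {
  key <- function(m) sort(apply(m, 1L, paste, collapse = ","))
  identical(key(concrete_spacings(p)),
            key(concrete_spacings(reverse_pattern(p))))
}

# Span (in residues) of each concrete spacing row.
spacing_spans <- function(p) {
  m <- concrete_spacings(p)
  as.integer(p$n_phi + rowSums(m))
}

# TRUE when a class name belongs to the class-1 family (either orientation).
is_class1_family <- function(class_name) {
  class_name %in% c(CLASS1_PLUS, CLASS1_MINUS)
}
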