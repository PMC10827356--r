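#' Parse a molecular formula in Hill notation
#'
#' Turns a formula string such as `"C6HF9O6"` into a `mol_formula` object: a
#' named integer vector of element counts. Dot-separated multi-component
#' formulas (`"C4F7O2.Na"`) are merged by summing counts, mirroring how a
#' multi-fragment substance record contributes a single record-level formula.
#'
#' @param text A single formula string. Element symbols must start with an
#'   uppercase letter; an omitted count means 1; counts must be positive.
#' @return A `mol_formula` object (named integer vector of counts, with the
#'   original string kept in the `"source_text"` attribute).
#' @examples
#' parse_formula("C6HF9O6")
#' parse_formula("C4F7O2.Na")
#' @export
parse_formula <- function(text) {
  if (length(text) != 1L || !is.character(text) || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("`text` must be a single non-empty formula string", call. = FALSE)
  }
  raw <- trimws(text)
  counts <- integer(0)
  for (part in strsplit(raw, ".", fixed = TRUE)[[1]]) {
    if (!nzchar(part)) {
      stop("empty component in formula '", raw, "'", call. = FALSE)
    }
    pos <- 1L
    n <- nchar(part)
    while (pos <= n) {
      m <- regmatches(
        substr(part, pos, n),
        regexpr("^([A-Z][a-z]?)([0-9]*)", substr(part, pos, n))
      )
      if (length(m) == 0L || !nzchar(m)) {
        stop("malformed formula token at position ", pos, " in '", part, "'",
             call. = FALSE)
      }
      sym <- sub("[0-9]*$", "", m)
      num <- sub("^[A-Za-z]+", "", m)
      # Greedy two-letter match can swallow a wrong pair ("CO" vs "Co"): Hill
      # strings are case-sensitive, so trust the case as written.
      if (!is_known_element(sym)) {
        # retry as one-letter symbol followed by a lowercase error
        stop("unknown element symbol '", sym, "' at position ", pos,
             " in '", part, "'", call. = FALSE)
      }
      cnt <- if (nzchar(num)) suppressWarnings(as.integer(num)) else 1L
      if (is.na(cnt) || cnt < 1L) {
        stop("invalid count '", num, "' for element ", sym, " at position ",
             pos, " in '", part, "'", call. = FALSE)
      }
      counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + cnt
      pos <- pos + nchar(m)
    }
  }
  new_mol_formula(counts, source_text = raw)
}

new_mol_formula <- function(counts, source_text = NULL) {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  counts <- counts[counts > 0]
  if (length(counts) == 0L) {
    stop("a molecular formula must contain at least one atom", call. = FALSE)
  }
  out <- structure(as.integer(counts), names = names(counts),
                   class = "mol_formula")
  attr(out, "source_text") <- source_text
  out
}

#' @export
format.mol_formula <- function(x, ...) {
  counts <- as.integer(x)
  names(counts) <- names(unclass(x))
  # Hill order: C, H, then alphabetical; alphabetical when no carbon.
  syms <- names(counts)
  if ("C" %in% syms) {
    ord <- c(
      "C", if ("H" %in% syms) "H",
      sort(setdiff(syms, c("C", "H")))
    )
  } else {
    ord <- sort(syms)
  }
  paste0(ord, ifelse(counts[ord] > 1L, counts[ord], ""), collapse = "")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<mol_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.mol_formula <- function(x, ...) format(x)

formula_count <- function(formula, element) {
  counts <- unclass(formula)
  if (element %in% names(counts)) unname(counts[[element]]) else 0L
}

as_mol_formula <- function(x) {
  if (inherits(x, "mol_formula")) return(x)
  if (is.character(x)) return(parse_formula(x))
  if (is.numeric(x) && !is.null(names(x))) return(new_mol_formula(x))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a molecular formula", call. = FALSE)
}

#' Fluorine fraction of a formula by atom count
#'
#' The fluorine atom count divided by the total atom count of the formula,
#' optionally excluding hydrogen from the denominator. The hydrogen-free
#' variant is the quantity thresholded (at 30%) by the combined
#' substructure-plus-fluorine definition; no rounding is applied here.
#'
#' @param formula A `mol_formula`, a formula string, or a named count vector.
#' @param include_h Count hydrogen atoms in the denominator? Default `FALSE`.
#' @return A fraction in `[0, 1]`.
#' @examples
#' fluorine_atom_fraction("C6HF9O6")                  # 9/21
#' fluorine_atom_fraction("C6HF9O6", include_h = TRUE) # 9/22
#' @export
fluorine_atom_fraction <- function(formula, include_h = FALSE) {
  formula <- as_mol_formula(formula)
  nf <- formula_count(formula, "F")
  total <- sum(unclass(formula))
  if (!include_h) total <- total - formula_count(formula, "H")
  if (total == 0L) {
    warning("formula contains only hydrogen; fluorine fraction defined as 0")
    return(0)
  }
  nf / total
}

#' Fluorine mass fraction of a formula
#'
#' Mass of fluorine over the total molecular weight, all atoms (hydrogen
#' included). Two mass tables are available: standard IUPAC atomic weights
#' and integer nucleon counts (F = 19, C = 12, ...) that reproduce
#' back-of-the-envelope arithmetic exactly.
#'
#' @inheritParams fluorine_atom_fraction
#' @param masses `"iupac"` (default) or `"integer"`.
#' @return A fraction in `[0, 1]`.
#' @examples
#' fluorine_mass_fraction("C4HF7O2")                      # PFBA, ~0.621
#' fluorine_mass_fraction("C4HF7O2", masses = "integer")  # 133/214
#' @export
fluorine_mass_fraction <- function(formula, masses = c("iupac", "integer")) {
  masses <- match.arg(masses)
  formula <- as_mol_formula(formula)
  counts <- unclass(formula)
  w <- atomic_weight(names(counts), masses = masses)
  total <- sum(counts * w)
  (formula_count(formula, "F") * atomic_weight("F", masses)) / total
}

#' Fluorine-to-carbon ratio of a formula
#'
#' `nF / nC`; returns `NA` (an undefined marker, not an error) when the
#' formula has no carbon. The PFAS structures list v1 requires this ratio to
#' be at least 0.5.
#'
#' @inheritParams fluorine_atom_fraction
#' @return A non-negative number, or `NA` when the formula is carbon-free.
#' @examples
#' f_to_c_ratio("C4HF7O2") # 1.75
#' f_to_c_ratio("F2S")     # NA
#' @export
f_to_c_ratio <- function(formula) {
  formula <- as_mol_formula(formula)
  nc <- formula_count(formula, "C")
  if (nc == 0L) return(NA_real_)
  formula_count(formula, "F") / nc
}

#' Fluorine descriptors for a set of formulas
#'
#' Data-frame-first wrapper computing every fluorine-content descriptor for a
#' vector or column of Hill-notation formulas: fluorine count, atom-count
#' fractions excluding/including hydrogen, mass fraction, and the
#' fluorine-to-carbon ratio.
#'
#' @param data A data frame with a formula column, or a character vector of
#'   formula strings.
#' @param formula Column holding the formula strings (tidy-eval); ignored when
#'   `data` is a character vector.
#' @param masses Mass table for the mass fraction, see
#'   [fluorine_mass_fraction()].
#' @return The input data frame (or a new tibble with a `formula` column) with
#'   columns `f_count`, `atom_fraction_excl_h`, `atom_fraction_incl_h`,
#'   `mass_fraction`, `f_to_c_ratio` appended.
#' @examples
#' fluorine_metrics(c(PFBA = "C4HF7O2", TFE = "C2F4"))
#' @export
fluorine_metrics <- function(data, formula = formula,
                             masses = c("iupac", "integer")) {
  masses <- match.arg(masses)
  if (is.character(data)) {
    data <- tibble::tibble(
      id = if (is.null(names(data))) as.character(seq_along(data))
           else names(data),
      formula = unname(data)
    )
    fcol <- data$formula
  } else {
    fcol <- dplyr::pull(data, {{ formula }})
  }
  parsed <- lapply(fcol, parse_formula)
  dplyr::bind_cols(
    tibble::as_tibble(data),
    tibble::tibble(
      f_count = vapply(parsed, formula_count, integer(1), element = "F"),
      atom_fraction_excl_h =
        vapply(parsed, fluorine_atom_fraction, numeric(1), include_h = FALSE),
      atom_fraction_incl_h =
        vapply(parsed, fluorine_atom_fraction, numeric(1), include_h = TRUE),
      mass_fraction =
        vapply(parsed, fluorine_mass_fraction, numeric(1), masses = masses),
      f_to_c_ratio = vapply(parsed, f_to_c_ratio, numeric(1))
    )
  )
}
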