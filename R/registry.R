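#' Define a PFAS definition as data
#'
#' A definition combines substructure patterns, an optional molecular-formula
#' fluorine rule, and exclusion filters. The combination logic is fixed:
#' a record is positive iff (any pattern matches OR the formula rule passes)
#' AND every filter passes.
#'
#' @param id Unique definition identifier.
#' @param label Human-readable name.
#' @param patterns List of [pattern_spec()] objects (possibly empty).
#' @param formula_rule `NULL`, or a list with `threshold` (fraction in (0,1])
#'   and `include_h` (logical): the record passes when its fluorine
#'   atom-count fraction is `>= threshold`.
#' @param filters Character vector drawn from `"no_radical"`,
#'   `"require_cf_bond"`, `"no_charged"`, `"no_isotope"`, `"f_count_range"`,
#'   `"f_to_c_min"`.
#' @param filter_params Named list of parameters for filters that need them:
#'   `f_count_range` (length-2 integer) and `f_to_c_min` (number).
#' @param provenance Optional citation note.
#' @return A `definition_spec` object.
#' @export
definition_spec <- function(id, label = id, patterns = list(),
                            formula_rule = NULL, filters = character(0),
                            filter_params = list(), provenance = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(patterns) == 0L && is.null(formula_rule)) {
    stop("definition '", id, "' needs at least one pattern or a formula rule",
         call. = FALSE)
  }
  if (!all(vapply(patterns, inherits, logical(1), "pattern_spec"))) {
    stop("`patterns` must be a list of pattern_spec objects", call. = FALSE)
  }
  pids <- vapply(patterns, `[[`, character(1), "id")
  if (anyDuplicated(pids)) {
    stop("duplicate pattern id(s) in definition '", id, "': ",
         paste(unique(pids[duplicated(pids)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(formula_rule)) {
    stopifnot(is.list(formula_rule), is.numeric(formula_rule$threshold),
              formula_rule$threshold > 0, formula_rule$threshold <= 1,
              is.logical(formula_rule$include_h))
  }
  known_filters <- c("no_radical", "require_cf_bond", "no_charged",
                     "no_isotope", "f_count_range", "f_to_c_min")
  bad <- setdiff(filters, known_filters)
  if (length(bad) > 0L) {
    stop("unknown filter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if ("f_count_range" %in% filters &&
      length(filter_params$f_count_range) != 2L) {
    stop("filter 'f_count_range' needs filter_params$f_count_range = c(lo, hi)",
         call. = FALSE)
  }
  if ("f_to_c_min" %in% filters && !is.numeric(filter_params$f_to_c_min)) {
    stop("filter 'f_to_c_min' needs filter_params$f_to_c_min", call. = FALSE)
  }
  names(patterns) <- pids
  structure(list(id = id, label = label, patterns = patterns,
                 formula_rule = formula_rule, filters = filters,
                 filter_params = filter_params, provenance = provenance),
            class = "definition_spec")
}

#' @export
print.definition_spec <- function(x, ...) {
  cat("<definition_spec> ", x$id, ": ", x$label, "\n", sep = "")
  cat("  patterns: ",
      if (length(x$patterns)) paste(names(x$patterns), collapse = ", ")
      else "(none)", "\n", sep = "")
  if (!is.null(x$formula_rule)) {
    cat("  formula rule: fluorine atom fraction (",
        if (x$formula_rule$include_h) "incl" else "excl",
        ". H) >= ", x$formula_rule$threshold, "\n", sep = "")
  }
  if (length(x$filters)) {
    cat("  filters: ", paste(x$filters, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Built-in PFAS definitions
#'
#' The codified definitions shipped with the package:
#'
#' * `oecd2021` — at least one fully fluorinated methyl or methylene carbon
#'   (saturated, no attached H/Cl/Br/I).
#' * `oecd2018` — a perfluoroalkyl moiety of three or more carbons
#'   (`-CnF2n-`, n >= 3) or a perfluoroalkylether moiety
#'   (`-CnF2n-O-CmF2m-`, n, m >= 1).
#' * `tsca2021` — the unit `R-CF2-CF(R')R''`, both carbons saturated, no R
#'   group hydrogen (fluorine/halogen R groups permitted).
#' * `pfasstruct_v1` — two adjacent CF2 groups (chain or ring), 4-1000
#'   fluorines in the formula, F:C ratio >= 0.5; charged species, radicals
#'   and isotope-labelled structures excluded.
#' * `pfasstruct_v4` — the reconstructed six-substructure registry of the
#'   EPA PFAS structures list v4 (see the package vignette for the
#'   reconstruction rationale); config-overridable.
#' * `ccl5` — the three Drinking Water Contaminant Candidate List 5 units:
#'   `R-CF2-CF(R')R''`, `R-CF2-O-CF2-R'`, `CF3-C(CF3)(R)R'`, all saturated,
#'   no hydrogen R groups.
#' * `pfasstruct_v5` — the combined definition: fluorine atom-count fraction
#'   (hydrogen excluded) >= 30% OR any of four substructures
#'   (CF2-CF unit, adjacent CF2-CF2, bis-CF3 quaternary unit, CF2-Q-CF2 with
#'   Q in B/O/N/P/S/Si), excluding free radicals and structures without a
#'   carbon-fluorine bond.
#'
#' @return A named list of `definition_spec` objects.
#' @examples
#' names(builtin_definitions())
#' @export
builtin_definitions <- function() {
  tsca_unit <- pattern_spec(
    "cf2_cf_unit", "cf2_pair", min_f_a = 2L, min_f_b = 1L,
    label = "R-CF2-CF(R')R'' with saturated carbons and no hydrogen R groups",
    smarts = "[CX4H0](F)(F)[CX4H0]F"
  )
  adj_cf2 <- pattern_spec(
    "adjacent_cf2", "cf2_pair", min_f_a = 2L, min_f_b = 2L,
    label = "two adjacent perfluorinated methylene carbons (chain or ring)",
    smarts = "[CX4H0](F)(F)[CX4H0](F)F"
  )
  cf2_o_cf2 <- pattern_spec(
    "cf2_o_cf2", "cf2_hetero_cf2", hetero = "O",
    label = "perfluorinated ether unit R-CF2-O-CF2-R'",
    smarts = "[CX4H0](F)(F)O[CX4H0](F)F"
  )
  bis_cf3_unit <- pattern_spec(
    "bis_cf3", "bis_cf3",
    label = "CF3-C(CF3)(R)R' with saturated carbons and no hydrogen R groups",
    smarts = "FC(F)(F)[CX4H0]C(F)(F)F"
  )

  list(
    oecd2021 = definition_spec(
      "oecd2021", "OECD (2021): at least one fully fluorinated methyl or methylene carbon",
      patterns = list(pattern_spec(
        "fully_fluorinated_carbon", "fully_fluorinated_carbon",
        label = "saturated carbon with >=2 F and no attached H/Cl/Br/I",
        smarts = "[CX4H0;!$(C[Cl,Br,I])](F)F"
      )),
      provenance = "OECD terminology report, 2021 revision"
    ),
    oecd2018 = definition_spec(
      "oecd2018", "OECD (2018): perfluoroalkyl moiety of >=3 carbons or perfluoroalkylether",
      patterns = list(
        pattern_spec("perfluoroalkyl_c3", "perfluoroalkyl_run", min_run = 3L,
                     label = "-CnF2n- run of three or more carbons"),
        cf2_o_cf2
      ),
      provenance = "OECD global PFAS database, 2018"
    ),
    tsca2021 = definition_spec(
      "tsca2021", "TSCA (2021) working definition: R-CF2-CF(R')R'' unit",
      patterns = list(tsca_unit),
      provenance = "USEPA TSCA section 8(a)(7) proposed rule, June 2021"
    ),
    pfasstruct_v1 = definition_spec(
      "pfasstruct_v1", "PFAS structures list v1 (2018): adjacent CF2 pair with formula gates",
      patterns = list(pattern_spec(
        "adjacent_cf2_groups", "cf2_pair", min_f_a = 2L, min_f_b = 2L,
        allow_h_a = TRUE, allow_h_b = TRUE,
        label = "two adjacent CF2 groups (>=2 F each), chain or ring",
        smarts = "C(F)(F)C(F)F"
      )),
      filters = c("f_count_range", "f_to_c_min", "no_charged", "no_radical",
                  "no_isotope"),
      filter_params = list(f_count_range = c(4L, 1000L), f_to_c_min = 0.5),
      provenance = "EPA Dashboard PFASSTRUCT v1 filter description, March 2018"
    ),
    pfasstruct_v4 = definition_spec(
      "pfasstruct_v4", "PFAS structures list v4 (2021): reconstructed substructure registry",
      patterns = list(
        s1_adjacent_cf2 = pattern_spec(
          "s1_adjacent_cf2", "cf2_pair", min_f_a = 2L, min_f_b = 2L,
          allow_h_a = TRUE, allow_h_b = TRUE,
          label = "two adjacent CF2 groups (>=2 F each, hydrogen permitted), carried forward from the v1 filter",
          smarts = "C(F)(F)C(F)F"
        ),
        s2_perfluoroethyl = pattern_spec(
          "s2_perfluoroethyl", "cf2_pair", min_f_a = 3L, min_f_b = 2L,
          label = "perfluoroethyl CF3-CF2 unit (structural subset of S1)",
          smarts = "FC(F)(F)[CX4H0](F)F"
        ),
        s3_tsca_unit = tsca_unit,
        s4_bis_cf3_branched = pattern_spec(
          "s4_bis_cf3_branched", "bis_cf3", allow_h_central = TRUE,
          label = "branched bis-trifluoromethyl unit CF3-C(CF3)<",
          smarts = "FC(F)(F)[CX4]C(F)(F)F"
        ),
        s5_cf2_cf_h = pattern_spec(
          "s5_cf2_cf_h", "cf2_pair", min_f_a = 2L, min_f_b = 1L,
          allow_h_b = TRUE, require_h_b = TRUE,
          label = "CF2-CF(H) unit: hydrogen on the CF carbon (not in TSCA2021)",
          smarts = "[CX4H0](F)(F)[CX4;!H0]F"
        ),
        s7_perfluoro_ether = cf2_o_cf2
      ),
      provenance = "EPA Dashboard PFASSTRUCT v4; substructure figure reconstructed from its textual description"
    ),
    ccl5 = definition_spec(
      "ccl5", "Drinking Water Contaminant Candidate List 5: three substructures",
      patterns = list(tsca_unit, cf2_o_cf2, bis_cf3_unit),
      provenance = "USEPA CCL5 final rule PFAS definition"
    ),
    pfasstruct_v5 = definition_spec(
      "pfasstruct_v5", "PFAS structures list v5 (proposed): four substructures OR >=30% fluorine by atom count",
      patterns = list(
        s1_cf2_cf = tsca_unit,
        s2_adjacent_cf2 = adj_cf2,
        s3_bis_cf3 = bis_cf3_unit,
        s4_cf2_q_cf2 = pattern_spec(
          "s4_cf2_q_cf2", "cf2_hetero_cf2", hetero = c("B", "O", "N", "P", "S", "Si"),
          label = "R-CF2-Q-CF2-R' with heteroatom Q in {B, O, N, P, S, Si}",
          smarts = "[CX4H0](F)(F)[#5,#8,#7,#15,#16,#14][CX4H0](F)F"
        )
      ),
      formula_rule = list(threshold = 0.30, include_h = FALSE),
      filters = c("no_radical", "require_cf_bond"),
      provenance = "proposed PFASSTRUCT v5: combined substructure + fluorine-fraction definition"
    )
  )
}

# resolve definition ids / spec lists to a named list of definition_spec
as_definition_list <- function(definitions) {
  if (inherits(definitions, "definition_spec")) {
    definitions <- list(definitions)
  }
  builtin <- NULL
  out <- lapply(definitions, function(d) {
    if (inherits(d, "definition_spec")) return(d)
    if (is.character(d) && length(d) == 1L) {
      if (is.null(builtin)) builtin <<- builtin_definitions()
      if (!d %in% names(builtin)) {
        stop("unknown definition id '", d, "'; built-ins are: ",
             paste(names(builtin), collapse = ", "), call. = FALSE)
      }
      return(builtin[[d]])
    }
    stop("`definitions` must be definition_spec objects or built-in ids",
         call. = FALSE)
  })
  ids <- vapply(out, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate definition id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(out, ids)
}

#' Load a definition registry from a YAML or JSON config
#'
#' Reads user-defined (or overridden) definitions from a config file and
#' merges them over the built-ins: a config block whose `id` matches a
#' built-in replaces it; new ids are appended. An empty config returns the
#' built-ins unchanged. Any invalid pattern or duplicate id aborts the load.
#'
#' Config schema (YAML):
#' ```yaml
#' definitions:
#'   - id: my_def
#'     label: Example
#'     patterns:
#'       - {id: p1, kind: cf2_pair, min_f_a: 2, min_f_b: 2}
#'     formula_rule: {threshold: 0.30, include_h: false}
#'     filters: [no_radical, require_cf_bond]
#'     filter_params: {f_count_range: [4, 1000]}
#' ```
#'
#' @param config Path to a `.yaml`/`.yml`/`.json` file, or an already-parsed
#'   list with a `definitions` element.
#' @param base Definitions to merge over; default [builtin_definitions()].
#' @return A named list of `definition_spec` objects.
#' @export
load_registry <- function(config, base = builtin_definitions()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("registry config not found: ", config, call. = FALSE)
    }
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  blocks <- config$definitions
  if (is.null(blocks)) return(base)
  specs <- lapply(blocks, function(b) {
    if (is.null(b$id)) stop("registry block without an 'id'", call. = FALSE)
    patterns <- lapply(b$patterns, function(pp) {
      args <- pp[setdiff(names(pp), c("id", "kind", "label", "smarts",
                                      "provenance"))]
      do.call(pattern_spec, c(
        list(id = pp$id, kind = pp$kind), args,
        list(label = pp$label %||% pp$id, smarts = pp$smarts,
             provenance = pp$provenance)
      ))
    })
    fr <- b$formula_rule
    if (!is.null(fr)) {
      fr <- list(threshold = as.numeric(fr$threshold),
                 include_h = isTRUE(fr$include_h))
    }
    definition_spec(
      id = b$id, label = b$label %||% b$id, patterns = patterns,
      formula_rule = fr,
      filters = as.character(b$filters %||% character(0)),
      filter_params = b$filter_params %||% list(),
      provenance = b$provenance
    )
  })
  ids <- vapply(specs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate definition id(s) in config: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  out <- base
  for (s in specs) out[[s$id]] <- s
  out
}

#' Validate a definition registry
#'
#' @param specs A list of `definition_spec` objects.
#' @return A tibble with one row per definition: id, number of patterns,
#'   whether a formula rule is present, filters, and any problems found
#'   (empty string when valid).
#' @export
validate_registry <- function(specs) {
  specs <- as_definition_list(specs)
  rows <- purrr::imap(specs, function(d, id) {
    problems <- character(0)
    if (!identical(d$id, id)) problems <- c(problems, "list name != id")
    if (length(d$patterns) == 0L && is.null(d$formula_rule)) {
      problems <- c(problems, "no patterns and no formula rule")
    }
    tibble::tibble(
      id = d$id,
      n_patterns = length(d$patterns),
      has_formula_rule = !is.null(d$formula_rule),
      filters = paste(d$filters, collapse = ","),
      problems = paste(problems, collapse = "; ")
    )
  })
  dplyr::bind_rows(rows)
}
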