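#' Classify one structure under one PFAS definition
#'
#' Evaluates a definition against a parsed structure and returns the verdict
#' with full evidence: every filter outcome, the formula-rule fraction, and
#' every matching pattern with its matched atom tuples. The combination logic
#' is (any pattern OR formula rule) AND all filters.
#'
#' Multicomponent policy: substructure patterns are inherently per-component
#' (an embedding cannot span disconnected fragments). The formula rule is
#' evaluated per component by default — a salt or mixture is positive when
#' any single fragment is sufficiently fluorinated — or on the whole-record
#' formula with `policy = "whole_record"`, matching a registry search over
#' record-level molecular formulas. Filters that read the formula
#' (fluorine-count range, F:C ratio) always use the whole-record formula;
#' radical/charge/isotope/C-F-bond filters see all components.
#'
#' @param record A `molecule_record` (see [parse_structure()]).
#' @param definition A `definition_spec` or a built-in definition id.
#' @param policy `"per_component"` (default) or `"whole_record"` for the
#'   formula rule.
#' @return A `classification_result`: list with `record_id`, `definition_id`,
#'   `is_pfas`, `evidence` (tibble: kind, id, passed, detail, value), and
#'   `metrics` (fluorine descriptors of the whole-record formula).
#' @examples
#' rec <- parse_structure("FC(F)=C(F)F", "tetrafluoroethene")
#' classify(rec, "pfasstruct_v5")$is_pfas
#' classify(rec, "oecd2021")$is_pfas
#' @export
classify <- function(record, definition,
                     policy = c("per_component", "whole_record")) {
  policy <- match.arg(policy)
  assert_record_ok(record)
  definition <- as_definition_list(list(definition))[[1]]

  metrics <- record_metrics(record)
  profile <- profile_carbons(record)
  evidence <- list()
  add_ev <- function(kind, id, passed, detail, value = NA_real_) {
    evidence[[length(evidence) + 1L]] <<- tibble::tibble(
      kind = kind, id = id, passed = passed, detail = detail,
      value = as.numeric(value)
    )
  }

  filters_pass <- TRUE
  for (f in definition$filters) {
    res <- switch(f,
      no_radical = {
        bad <- is_radical(record)
        list(!bad, if (bad) "structure is a free radical" else "not a radical")
      },
      require_cf_bond = {
        ok <- has_cf_bond(record)
        list(ok, if (ok) "carbon-fluorine bond present" else "no carbon-fluorine bond")
      },
      no_charged = {
        q <- net_charge(record)
        list(q == 0L, paste0("net formal charge ", q))
      },
      no_isotope = {
        bad <- has_isotope_label(record)
        list(!bad, if (bad) "isotope-labelled atoms present" else "no isotope labels")
      },
      f_count_range = {
        rng <- definition$filter_params$f_count_range
        nf <- metrics$f_count
        list(nf >= rng[1] && nf <= rng[2],
             paste0("fluorine count ", nf, " vs allowed [", rng[1], ", ",
                    rng[2], "]"))
      },
      f_to_c_min = {
        r <- metrics$f_to_c_ratio
        ok <- !is.na(r) && r >= definition$filter_params$f_to_c_min
        list(ok, paste0("F:C ratio ", signif(r, 4), " vs minimum ",
                        definition$filter_params$f_to_c_min))
      }
    )
    add_ev("filter", f, res[[1]], res[[2]])
    filters_pass <- filters_pass && res[[1]]
  }

  formula_pass <- FALSE
  if (!is.null(definition$formula_rule)) {
    fr <- definition$formula_rule
    fracs <- if (policy == "per_component") {
      vapply(record$component_formulas, fluorine_atom_fraction, numeric(1),
             include_h = fr$include_h)
    } else {
      fluorine_atom_fraction(record$formula, include_h = fr$include_h)
    }
    best <- max(fracs)
    formula_pass <- best >= fr$threshold
    add_ev("formula", "fluorine_fraction", formula_pass,
           paste0("fluorine atom fraction (",
                  if (fr$include_h) "incl" else "excl", ". H, ", policy,
                  ") = ", signif(best, 4), " vs threshold ", fr$threshold),
           best)
  }

  pattern_pass <- FALSE
  for (pat in definition$patterns) {
    m <- match_pattern(record, pat, profile = profile)
    hit <- length(m) > 0L
    add_ev("pattern", pat$id, hit,
           if (hit) {
             paste0(length(m), " match(es): ",
                    paste(vapply(m, function(x) paste0("(", paste(x, collapse = ","), ")"),
                                 character(1)), collapse = " "))
           } else "no match",
           length(m))
    pattern_pass <- pattern_pass || hit
  }

  structure(
    list(
      record_id = record$id,
      definition_id = definition$id,
      is_pfas = (pattern_pass || formula_pass) && filters_pass,
      evidence = dplyr::bind_rows(evidence),
      metrics = metrics
    ),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result> ", x$record_id, " / ", x$definition_id, ": ",
      if (x$is_pfas) "PFAS" else "not PFAS", "\n", sep = "")
  print(x$evidence)
  invisible(x)
}

# whole-record fluorine metrics as a one-row tibble
record_metrics <- function(record) {
  f <- record$formula
  tibble::tibble(
    formula = format(f),
    f_count = formula_count(f, "F"),
    atom_fraction_excl_h = fluorine_atom_fraction(f, include_h = FALSE),
    atom_fraction_incl_h = fluorine_atom_fraction(f, include_h = TRUE),
    mass_fraction = fluorine_mass_fraction(f),
    f_to_c_ratio = f_to_c_ratio(f)
  )
}

#' Classify a compound library under a set of PFAS definitions
#'
#' The package's main verb. Takes structures as a data frame (with a SMILES
#' column), a character vector of SMILES, or a list of parsed records;
#' classifies every record under every definition; and returns a tidy tibble
#' with one row per record x definition, the verdict, the supporting
#' evidence, and the whole-record fluorine metrics. Records that fail to
#' parse are dropped from the classification and reported in the
#' `"skipped"` attribute (and a message).
#'
#' @param data A data frame with SMILES and id columns, a character vector of
#'   SMILES (optionally named), or a list of `molecule_record` objects.
#' @param definitions Definitions to apply: `definition_spec` objects or
#'   built-in ids. Default: all built-ins.
#' @param smiles,id Column names used when `data` is a data frame.
#' @param policy Formula-rule multicomponent policy, see [classify()].
#' @return A tibble with columns `record_id`, `definition_id`, `is_pfas`,
#'   `evidence` (list-column of tibbles), `formula`, `f_count`,
#'   `atom_fraction_excl_h`, `atom_fraction_incl_h`, `mass_fraction`,
#'   `f_to_c_ratio`. Attribute `"skipped"` holds a tibble of parse failures.
#' @examples
#' pfas_classify(c(PFBA = "OC(=O)C(F)(F)C(F)(F)C(F)(F)F"),
#'               definitions = c("oecd2021", "pfasstruct_v5"))
#' @export
pfas_classify <- function(data, definitions = builtin_definitions(),
                          smiles = "smiles", id = "id",
                          policy = c("per_component", "whole_record")) {
  policy <- match.arg(policy)
  records <- as_record_list(data, smiles_col = smiles, id_col = id)
  defs <- as_definition_list(definitions)
  if (length(defs) == 0L) stop("no definitions supplied", call. = FALSE)

  ok <- vapply(records, record_ok, logical(1))
  skipped <- tibble::tibble(
    record_id = unname(vapply(records[!ok], `[[`, character(1), "id")),
    message = unname(vapply(records[!ok], `[[`, character(1), "message"))
  )
  if (nrow(skipped) > 0L) {
    message(nrow(skipped), " record(s) skipped due to parse errors")
  }
  rows <- purrr::map(records[ok], function(rec) {
    purrr::map(defs, function(d) {
      res <- classify(rec, d, policy = policy)
      dplyr::bind_cols(
        tibble::tibble(record_id = res$record_id,
                       definition_id = res$definition_id,
                       is_pfas = res$is_pfas,
                       evidence = list(res$evidence)),
        res$metrics
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (nrow(rows) == 0L) {
    rows <- tibble::tibble(
      record_id = character(0), definition_id = character(0),
      is_pfas = logical(0), evidence = list(), formula = character(0),
      f_count = integer(0), atom_fraction_excl_h = numeric(0),
      atom_fraction_incl_h = numeric(0), mass_fraction = numeric(0),
      f_to_c_ratio = numeric(0)
    )
  }
  attr(rows, "skipped") <- skipped
  rows
}

#' Cross-definition comparison matrix
#'
#' Classifies records under several definitions and arranges the verdicts as
#' a records x definitions boolean table with per-definition totals — the
#' shape used for set comparisons between PFAS definitions.
#'
#' @inheritParams pfas_classify
#' @param classified Optionally, an existing [pfas_classify()] result to
#'   pivot instead of re-classifying.
#' @return A `pfas_matrix` object: list with `matrix` (tibble, one row per
#'   record, one logical column per definition), `totals` (named integer
#'   vector of column sums), `skipped` (parse-failure tibble), and
#'   `classified` (the long-form result).
#' @examples
#' m <- classify_all(c(CF4 = "FC(F)(F)F", methane = "C"),
#'                   definitions = c("oecd2021", "pfasstruct_v5"))
#' m$totals
#' @export
classify_all <- function(data, definitions = builtin_definitions(),
                         smiles = "smiles", id = "id",
                         policy = c("per_component", "whole_record"),
                         classified = NULL) {
  if (is.null(classified)) {
    classified <- pfas_classify(data, definitions, smiles = smiles, id = id,
                                policy = policy)
  }
  def_ids <- if (nrow(classified) > 0L) unique(classified$definition_id)
             else names(as_definition_list(definitions))
  wide <- classified |>
    dplyr::select("record_id", "definition_id", "is_pfas") |>
    tidyr::pivot_wider(names_from = "definition_id",
                       values_from = "is_pfas") |>
    # deterministic row order = input order
    dplyr::arrange(match(.data$record_id, unique(classified$record_id)))
  # an empty corpus must still carry one logical column per definition
  for (d in setdiff(def_ids, names(wide))) wide[[d]] <- logical(nrow(wide))
  totals <- vapply(wide[-1], sum, integer(1))
  structure(
    list(matrix = wide, totals = totals,
         skipped = attr(classified, "skipped") %||%
           tibble::tibble(record_id = character(0), message = character(0)),
         classified = classified),
    class = "pfas_matrix"
  )
}

#' @export
print.pfas_matrix <- function(x, ...) {
  cat("<pfas_matrix> ", nrow(x$matrix), " records x ",
      ncol(x$matrix) - 1L, " definitions\n", sep = "")
  cat("positives per definition:\n")
  print(x$totals)
  if (nrow(x$skipped) > 0L) {
    cat(nrow(x$skipped), "record(s) skipped (parse errors)\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PFAS comparison matrix
#'
#' @param x A `pfas_matrix`.
#' @param ... Unused.
#' @return Long-form tibble: `record_id`, `definition_id`, `is_pfas`.
#' @export
tidy.pfas_matrix <- function(x, ...) {
  tidyr::pivot_longer(x$matrix, -"record_id",
                      names_to = "definition_id", values_to = "is_pfas")
}

#' One-row summary of a PFAS comparison matrix
#'
#' @param x A `pfas_matrix`.
#' @param ... Unused.
#' @return Tibble with `n_records`, `n_definitions`, `n_skipped`, and one
#'   `n_<definition>` column of positives per definition.
#' @export
glance.pfas_matrix <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      n_records = nrow(x$matrix),
      n_definitions = ncol(x$matrix) - 1L,
      n_skipped = nrow(x$skipped)
    ),
    tibble::as_tibble(as.list(stats::setNames(
      as.integer(x$totals), paste0("n_", names(x$totals))
    )))
  )
}
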