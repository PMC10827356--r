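#' Parse a chemical structure into a molecule record
#'
#' Reads a SMILES string or an MDL V2000 molblock into a `molecule_record`:
#' the atom and bond tables, connected components (salt/mixture fragments),
#' and per-component plus whole-record molecular formulas. Implicit hydrogens
#' are materialised into the formula so that hydrogen-aware fluorine metrics
#' are meaningful for structure input.
#'
#' @param text A SMILES string, or a full V2000 molblock (auto-detected by the
#'   embedded connection-table counts line; use `format` to force).
#' @param id Identifier carried into all downstream results.
#' @param format `"auto"`, `"smiles"`, or `"molblock"`.
#' @param on_error `"record"` (default): a failed parse yields a record with
#'   `status = "parse_error"` so batch runs never abort; `"stop"`: raise the
#'   parse error (single-record workflows).
#' @return A `molecule_record`: list with `id`, `source`, `status`, `message`,
#'   `atoms` (tibble: element, aromatic, isotope, charge, implicit_h, radical,
#'   degree, component), `bonds` (tibble: a1, a2, order, aromatic), `formula`
#'   (whole record) and `component_formulas` (one per fragment).
#' @examples
#' rec <- parse_structure("C(F)(F)(C(F)(F)F)C(=O)O", id = "PFBA-like")
#' rec$formula
#' parse_structure("[Na+].[O-]C(=O)C(F)(F)F", id = "salt")$component_formulas
#' @export
parse_structure <- function(text, id = "mol",
                            format = c("auto", "smiles", "molblock"),
                            on_error = c("record", "stop")) {
  format <- match.arg(format)
  on_error <- match.arg(on_error)
  stopifnot(is.character(text), length(text) == 1L)
  if (format == "auto") {
    format <- if (grepl("\n", text, fixed = TRUE) &&
                  grepl("V2000", text, fixed = TRUE)) "molblock" else "smiles"
  }
  parsed <- tryCatch(
    if (format == "smiles") parse_smiles_graph(text) else parse_molblock(text),
    error = function(e) e
  )
  if (inherits(parsed, "error")) {
    if (on_error == "stop") stop(conditionMessage(parsed), call. = FALSE)
    return(structure(
      list(id = id, source = text, status = "parse_error",
           message = conditionMessage(parsed),
           atoms = NULL, bonds = NULL, formula = NULL,
           component_formulas = NULL),
      class = "molecule_record"
    ))
  }
  atoms <- parsed$atoms
  comp_ids <- sort(unique(atoms$component))
  component_formulas <- lapply(comp_ids, function(ci) {
    graph_formula(atoms, atoms$atom[atoms$component == ci])
  })
  names(component_formulas) <- paste0("component_", comp_ids)
  structure(
    list(id = id, source = text, status = "ok", message = NA_character_,
         atoms = atoms, bonds = parsed$bonds,
         formula = graph_formula(atoms),
         component_formulas = component_formulas),
    class = "molecule_record"
  )
}

#' @export
print.molecule_record <- function(x, ...) {
  cat("<molecule_record> ", x$id, " [", x$status, "]\n", sep = "")
  if (x$status == "ok") {
    cat("  formula: ", format(x$formula),
        "  atoms: ", nrow(x$atoms),
        "  components: ", length(x$component_formulas), "\n", sep = "")
  } else {
    cat("  ", x$message, "\n", sep = "")
  }
  invisible(x)
}

record_ok <- function(record) {
  inherits(record, "molecule_record") && identical(record$status, "ok")
}

assert_record_ok <- function(record) {
  if (!inherits(record, "molecule_record")) {
    stop("expected a molecule_record; see parse_structure()", call. = FALSE)
  }
  if (!identical(record$status, "ok")) {
    stop("record '", record$id, "' has parse_error status: ", record$message,
         call. = FALSE)
  }
  invisible(record)
}

#' Parse a batch of structures
#'
#' Vectorised wrapper over [parse_structure()]; parse failures become records
#' with `status = "parse_error"` and never abort the batch.
#'
#' @param texts Character vector of SMILES strings (or molblocks).
#' @param ids Identifiers; defaults to names of `texts` or sequential ids.
#' @inheritParams parse_structure
#' @return A list of `molecule_record` objects, named by id.
#' @export
parse_structures <- function(texts, ids = NULL,
                             format = c("auto", "smiles", "molblock")) {
  format <- match.arg(format)
  if (is.null(ids)) {
    ids <- if (!is.null(names(texts))) names(texts)
           else sprintf("mol_%d", seq_along(texts))
  }
  stopifnot(length(ids) == length(texts))
  out <- purrr::map2(unname(texts), ids, parse_structure, format = format)
  names(out) <- ids
  out
}

# coerce various inputs (record list, character SMILES vector, data frame with
# smiles/id columns) into a named list of molecule_records
as_record_list <- function(records, smiles_col = "smiles", id_col = "id") {
  if (inherits(records, "molecule_record")) return(stats::setNames(list(records), records$id))
  if (is.list(records) && all(vapply(records, inherits, logical(1), "molecule_record")) &&
      !is.data.frame(records)) {
    names(records) <- vapply(records, `[[`, character(1), "id")
    return(records)
  }
  if (is.character(records)) return(parse_structures(records))
  if (is.data.frame(records)) {
    if (!smiles_col %in% names(records)) {
      stop("data frame input needs a '", smiles_col, "' column", call. = FALSE)
    }
    ids <- if (id_col %in% names(records)) as.character(records[[id_col]])
           else sprintf("mol_%d", seq_len(nrow(records)))
    return(parse_structures(records[[smiles_col]], ids))
  }
  stop("cannot interpret `records` as molecule records", call. = FALSE)
}
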