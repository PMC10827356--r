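# Substructure pattern engine.
#
# PFAS definition substructures are small linear units over fluorinated,
# saturated carbons. Each built-in pattern is a parameterised structural kind
# matched directly on the carbon-profile table and bond list; the optional
# `smarts` field carries the equivalent SMARTS expression as a portable
# annotation (the test suite cross-checks the native matcher against an
# OpenBabel SMARTS search where available).

.PATTERN_KINDS <- c("fully_fluorinated_carbon", "perfluoroalkyl_run",
                    "cf2_pair", "cf2_hetero_cf2", "bis_cf3")

#' Define a substructure pattern
#'
#' @param id Unique pattern identifier within a definition/registry.
#' @param kind One of the structural kinds:
#'   * `fully_fluorinated_carbon` — a saturated -CF2-/-CF3 carbon with no
#'     attached H/Cl/Br/I; no parameters.
#'   * `perfluoroalkyl_run` — a run of `min_run` consecutive perfluorinated
#'     carbons (`-CnF2n-`); parameter `min_run` (default 3).
#'   * `cf2_pair` — the two-carbon unit A-B (single bond, both saturated);
#'     parameters `min_f_a` (default 2), `min_f_b` (default 1),
#'     `allow_h_a`/`allow_h_b` (default FALSE: the attachment positions carry
#'     no hydrogen, the "no R group can be hydrogen" reading; fluorine and
#'     other halogens are permitted R groups).
#'   * `cf2_hetero_cf2` — A-Q-B with Q a heteroatom from `hetero` (default
#'     `"O"`), both carbons saturated with >= `min_f` fluorines (default 2)
#'     and no hydrogen; single bonds throughout.
#'   * `bis_cf3` — CF3-C(CF3)(R)R': a saturated central carbon bearing two
#'     trifluoromethyl groups; parameter `allow_h_central` (default FALSE).
#' @param ... Parameters for the kind (see above).
#' @param label Human-readable description.
#' @param smarts Optional SMARTS annotation (not used for matching).
#' @param provenance Optional citation/origin note.
#' @return A `pattern_spec` object.
#' @examples
#' pattern_spec("tsca_unit", "cf2_pair", label = "R-CF2-CF(R')R'' unit")
#' @export
pattern_spec <- function(id, kind, ..., label = id, smarts = NULL,
                         provenance = NULL) {
  kind <- match.arg(kind, .PATTERN_KINDS)
  params <- list(...)
  defaults <- switch(kind,
    fully_fluorinated_carbon = list(),
    perfluoroalkyl_run = list(min_run = 3L),
    cf2_pair = list(min_f_a = 2L, min_f_b = 1L,
                    allow_h_a = FALSE, allow_h_b = FALSE,
                    require_h_a = FALSE, require_h_b = FALSE),
    cf2_hetero_cf2 = list(hetero = "O", min_f = 2L),
    bis_cf3 = list(allow_h_central = FALSE)
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown parameter(s) for pattern kind '", kind, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  params <- utils::modifyList(defaults, params)
  if (kind == "cf2_hetero_cf2") {
    # flatten config-sourced lists; catch YAML's unquoted N/B -> logical trap
    params$hetero <- as.character(unlist(params$hetero))
    bad <- params$hetero[!vapply(params$hetero, is_known_element, logical(1))]
    if (length(bad) > 0L) {
      stop("pattern '", id, "': hetero contains non-element value(s) ",
           paste0("'", bad, "'", collapse = ", "),
           " (quote symbols like \"N\" in YAML configs)", call. = FALSE)
    }
  }
  structure(list(id = id, kind = kind, params = params, label = label,
                 smarts = smarts, provenance = provenance),
            class = "pattern_spec")
}

#' @export
print.pattern_spec <- function(x, ...) {
  cat("<pattern_spec> ", x$id, " (", x$kind, ")\n  ", x$label, "\n", sep = "")
  invisible(x)
}

#' Match a substructure pattern against a structure
#'
#' Finds all distinct embeddings of a pattern in a molecule record, in
#' deterministic order (sorted by atom indices). Embeddings never span
#' disconnected components.
#'
#' @param record A `molecule_record`.
#' @param pattern A `pattern_spec`.
#' @param profile Optional precomputed [profile_carbons()] table (saves
#'   recomputation when matching many patterns).
#' @return A list of integer atom-index tuples (empty when no match).
#' @examples
#' rec <- parse_structure("FC(F)(F)C(F)(F)F", "C2F6")
#' match_pattern(rec, pattern_spec("pair", "cf2_pair", min_f_b = 2))
#' @export
match_pattern <- function(record, pattern, profile = NULL) {
  assert_record_ok(record)
  stopifnot(inherits(pattern, "pattern_spec"))
  if (is.null(profile)) profile <- profile_carbons(record)
  p <- pattern$params
  matches <- switch(pattern$kind,
    fully_fluorinated_carbon = {
      hits <- profile$atom[is_fully_fluorinated_carbon(profile)]
      lapply(hits, identity)
    },
    perfluoroalkyl_run = match_run(record, profile, p$min_run),
    cf2_pair = match_cf2_pair(record, profile, p),
    cf2_hetero_cf2 = match_cf2_hetero(record, profile, p),
    bis_cf3 = match_bis_cf3(record, profile, p)
  )
  matches[order(vapply(matches, function(m) paste(sprintf("%06d", m), collapse = ""),
                       character(1)))]
}

# perfluorinated run components of size >= min_run
match_run <- function(record, profile, min_run) {
  qualifies <- profile$saturated & profile$n_f >= 2L & profile$n_h == 0L &
    profile$n_other_halogen == 0L &
    profile$n_other_heavy ==
      vapply(profile$heavy_neighbors, function(h) sum(h == "C"), integer(1))
  q_atoms <- profile$atom[qualifies]
  if (length(q_atoms) == 0L) return(list())
  b <- record$bonds
  keep <- b$a1 %in% q_atoms & b$a2 %in% q_atoms
  g <- igraph::graph_from_data_frame(
    b[keep, c("a1", "a2")], directed = FALSE,
    vertices = data.frame(name = q_atoms)
  )
  comp <- igraph::components(g)
  members <- split(as.integer(igraph::V(g)$name), comp$membership)
  out <- Filter(function(m) length(m) >= min_run, members)
  unname(lapply(out, sort))
}

pair_ok <- function(profile, atom, min_f, allow_h, require_h = FALSE) {
  row <- match(atom, profile$atom)
  if (is.na(row)) return(FALSE) # not a carbon
  profile$saturated[row] && profile$n_f[row] >= min_f &&
    (allow_h || profile$n_h[row] == 0L) &&
    (!require_h || profile$n_h[row] >= 1L)
}

match_cf2_pair <- function(record, profile, p) {
  b <- record$bonds
  out <- list()
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != 1 || b$aromatic[k]) next
    for (pair in list(c(b$a1[k], b$a2[k]), c(b$a2[k], b$a1[k]))) {
      if (pair_ok(profile, pair[1], p$min_f_a, p$allow_h_a, p$require_h_a) &&
          pair_ok(profile, pair[2], p$min_f_b, p$allow_h_b, p$require_h_b)) {
        out[[length(out) + 1L]] <- pair
      }
    }
  }
  # a symmetric pair can embed in both orientations; keep unordered-unique
  unique(lapply(out, sort))
}

match_cf2_hetero <- function(record, profile, p) {
  atoms <- record$atoms
  nbr <- adjacency_list(record)
  q_atoms <- atoms$atom[atoms$element %in% p$hetero]
  out <- list()
  for (q in q_atoms) {
    inc <- nbr[[q]]
    cand <- inc$atom[inc$order == 1 &
                       vapply(inc$atom, pair_ok, logical(1),
                              profile = profile, min_f = p$min_f,
                              allow_h = FALSE)]
    if (length(cand) >= 2L) {
      pairs <- utils::combn(sort(cand), 2L, simplify = FALSE)
      for (pr in pairs) out[[length(out) + 1L]] <- c(pr[1], q, pr[2])
    }
  }
  out
}

match_bis_cf3 <- function(record, profile, p) {
  is_cf3 <- profile$saturated & profile$n_f == 3L
  cf3_atoms <- profile$atom[is_cf3]
  out <- list()
  for (i in seq_len(nrow(profile))) {
    if (!profile$saturated[i]) next
    if (!p$allow_h_central && profile$n_h[i] > 0L) next
    c_nbrs <- intersect(profile$carbon_neighbors[[i]], cf3_atoms)
    c_nbrs <- setdiff(c_nbrs, profile$atom[i])
    if (length(c_nbrs) >= 2L) {
      for (pr in utils::combn(sort(c_nbrs), 2L, simplify = FALSE)) {
        out[[length(out) + 1L]] <- c(pr[1], profile$atom[i], pr[2])
      }
    }
  }
  out
}
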