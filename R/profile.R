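#' Profile every carbon atom of a structure
#'
#' One row per carbon with the bookkeeping every structural PFAS predicate is
#' built from: saturation (all single bonds, non-aromatic), aromaticity,
#' attached fluorine / hydrogen (implicit + explicit) / other-halogen counts,
#' and the elements of remaining heavy neighbours. The counts are exact:
#' `n_f + n_h + n_other_halogen + n_other_heavy` equals the carbon's total
#' connection count (explicit degree plus implicit hydrogens).
#'
#' @param record A `molecule_record` with `status == "ok"`.
#' @return A tibble with columns `atom`, `component`, `saturated`, `aromatic`,
#'   `n_f`, `n_h`, `n_other_halogen`, `n_other_heavy`, `heavy_neighbors`
#'   (list-column of element symbols), `carbon_neighbors` (list-column of
#'   carbon atom indices), `n_connections`.
#' @examples
#' profile_carbons(parse_structure("FC(F)(F)F", "CF4"))
#' @export
profile_carbons <- function(record) {
  assert_record_ok(record)
  atoms <- record$atoms
  bonds <- record$bonds
  carbons <- atoms$atom[atoms$element == "C"]
  if (length(carbons) == 0L) {
    return(tibble::tibble(
      atom = integer(0), component = integer(0), saturated = logical(0),
      aromatic = logical(0), n_f = integer(0), n_h = integer(0),
      n_other_halogen = integer(0), n_other_heavy = integer(0),
      heavy_neighbors = list(), carbon_neighbors = list(),
      n_connections = integer(0)
    ))
  }
  nbr <- adjacency_list(record)
  rows <- lapply(carbons, function(a) {
    inc <- nbr[[a]]
    nbr_elem <- atoms$element[inc$atom]
    n_f <- sum(nbr_elem == "F")
    n_h_expl <- sum(nbr_elem == "H")
    n_hal <- sum(nbr_elem %in% .HALOGENS_OTHER)
    other <- nbr_elem != "F" & nbr_elem != "H"
    aromatic <- atoms$aromatic[a]
    saturated <- !aromatic && (length(inc$order) == 0L || all(inc$order == 1))
    tibble::tibble(
      atom = a,
      component = atoms$component[a],
      saturated = saturated,
      aromatic = aromatic,
      n_f = n_f,
      n_h = n_h_expl + atoms$implicit_h[a],
      n_other_halogen = n_hal,
      n_other_heavy = sum(other) - n_hal,
      heavy_neighbors = list(sort(nbr_elem[other])),
      carbon_neighbors = list(inc$atom[nbr_elem == "C"]),
      n_connections = length(inc$atom) + atoms$implicit_h[a]
    )
  })
  dplyr::bind_rows(rows)
}

# neighbour list: for each atom, the adjacent atom indices and bond orders
adjacency_list <- function(record) {
  atoms <- record$atoms
  bonds <- record$bonds
  out <- replicate(nrow(atoms),
                   list(atom = integer(0), order = numeric(0)),
                   simplify = FALSE)
  for (k in seq_len(nrow(bonds))) {
    a1 <- bonds$a1[k]; a2 <- bonds$a2[k]; o <- bonds$order[k]
    out[[a1]]$atom <- c(out[[a1]]$atom, a2)
    out[[a1]]$order <- c(out[[a1]]$order, o)
    out[[a2]]$atom <- c(out[[a2]]$atom, a1)
    out[[a2]]$order <- c(out[[a2]]$order, o)
  }
  out
}

#' Fully fluorinated carbon predicate
#'
#' TRUE for a saturated, non-aromatic carbon bearing at least two fluorines
#' and no attached hydrogen, chlorine, bromine or iodine — a perfluorinated
#' methyl (-CF3) or methylene (-CF2-) carbon, the minimal unit of the OECD
#' 2021 definition. `CF4` itself (four fluorines) qualifies.
#'
#' @param profile A carbon-profile tibble from [profile_carbons()] (or a
#'   subset of its rows).
#' @return A logical vector, one element per profile row.
#' @export
is_fully_fluorinated_carbon <- function(profile) {
  profile$saturated & !profile$aromatic & profile$n_f >= 2L &
    profile$n_h == 0L & profile$n_other_halogen == 0L
}

#' Does the structure contain any carbon-fluorine bond?
#'
#' @param record A `molecule_record`.
#' @return TRUE iff any C-F bond exists in any component.
#' @export
has_cf_bond <- function(record) {
  assert_record_ok(record)
  b <- record$bonds
  if (nrow(b) == 0L) return(FALSE)
  e1 <- record$atoms$element[b$a1]
  e2 <- record$atoms$element[b$a2]
  any((e1 == "C" & e2 == "F") | (e1 == "F" & e2 == "C"))
}

#' Is the structure a free radical?
#'
#' TRUE iff any atom carries an unpaired electron. For SMILES input radicals
#' are perceived from bracket-atom valence deficits (`[C](F)(F)F` is the
#' trifluoromethyl radical); for molblocks the `M  RAD` property line is used.
#'
#' @param record A `molecule_record`.
#' @return Logical flag.
#' @export
is_radical <- function(record) {
  assert_record_ok(record)
  any(record$atoms$radical > 0L)
}

#' Isotope-label and net-charge accessors
#'
#' `has_isotope_label()` is TRUE iff any atom has an explicit isotope mass
#' (deuterium, carbon-13, ...). `net_charge()` sums formal charges over all
#' components, so a complete salt is 0 while a bare anion is negative.
#'
#' @param record A `molecule_record`.
#' @return Logical flag / integer charge.
#' @export
has_isotope_label <- function(record) {
  assert_record_ok(record)
  any(!is.na(record$atoms$isotope))
}

#' @rdname has_isotope_label
#' @export
net_charge <- function(record) {
  assert_record_ok(record)
  sum(record$atoms$charge)
}

#' Longest perfluorinated-carbon run
#'
#' Length of the longest chain (or ring) of consecutive carbons that are
#' saturated, hydrogen- and other-halogen-free, carry at least two fluorines,
#' and whose remaining heavy neighbours are all carbon — the `-CnF2n-` moiety.
#' Terminal perfluoromethyl (-CF3) carbons satisfy those conditions and count
#' toward the run, so perfluorobutanoic acid (CF3CF2CF2-COOH) has run length
#' 3, matching the three-carbon perfluoroalkyl moiety threshold of the OECD
#' 2018 database definition.
#'
#' @param record A `molecule_record`.
#' @return A non-negative integer.
#' @export
max_perfluoromethylene_run <- function(record) {
  assert_record_ok(record)
  prof <- profile_carbons(record)
  qualifies <- prof$saturated & prof$n_f >= 2L & prof$n_h == 0L &
    prof$n_other_halogen == 0L & prof$n_other_heavy ==
      vapply(prof$heavy_neighbors, function(h) sum(h == "C"), integer(1))
  q_atoms <- prof$atom[qualifies]
  if (length(q_atoms) == 0L) return(0L)
  # each qualifying carbon has at most two carbon neighbours (>=2 F of 4
  # bonds), so the induced subgraph is a union of paths and cycles and the
  # longest run is simply the largest connected-component size
  b <- record$bonds
  keep <- b$a1 %in% q_atoms & b$a2 %in% q_atoms
  g <- igraph::graph_from_data_frame(
    b[keep, c("a1", "a2")], directed = FALSE,
    vertices = data.frame(name = q_atoms)
  )
  as.integer(max(igraph::components(g)$csize))
}

#' Trivially fluorinated structure predicate
#'
#' TRUE for structures whose only fluorination is one isolated
#' trifluoromethyl group (exactly three fluorines, all on one CF3 carbon) or
#' two trifluoromethyl groups that do not share a common carbon neighbour
#' (exactly six fluorines). Such structures are set aside when narrowing a
#' library to candidate PFAS missed by a substructure definition, because
#' isolated CF3 termini fit few PFAS definitions. Two CF3 groups attached to
#' the same carbon are retained (not trivial).
#'
#' @param record A `molecule_record`.
#' @return Logical flag.
#' @export
is_trivially_fluorinated <- function(record) {
  assert_record_ok(record)
  n_f_total <- formula_count(record$formula, "F")
  if (!n_f_total %in% c(3L, 6L)) return(FALSE)
  prof <- profile_carbons(record)
  cf3 <- prof$atom[prof$saturated & prof$n_f == 3L]
  if (n_f_total == 3L) {
    return(length(cf3) == 1L && sum(prof$n_f) == 3L)
  }
  # six fluorines: exactly two CF3 groups holding all of them
  if (length(cf3) != 2L || sum(prof$n_f) != 6L) return(FALSE)
  nbr1 <- prof$carbon_neighbors[prof$atom == cf3[1]][[1]]
  nbr2 <- prof$carbon_neighbors[prof$atom == cf3[2]][[1]]
  # trivial only when the CF3 carbons are NOT bonded to a shared carbon
  length(intersect(nbr1, nbr2)) == 0L
}
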