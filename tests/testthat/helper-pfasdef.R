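# Shared helpers for the test suite.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Independent recomputation of the fully-fluorinated-carbon predicate straight
# from the atom/bond tables, deliberately avoiding profile_carbons() and the
# pattern engine, so implementation and oracle cannot collapse onto the same
# code path.
oracle_has_ffc <- function(record) {
  atoms <- record$atoms
  bonds <- record$bonds
  for (a in atoms$atom[atoms$element == "C"]) {
    if (atoms$aromatic[a]) next
    rows <- which(bonds$a1 == a | bonds$a2 == a)
    if (any(bonds$order[rows] != 1)) next
    nbrs <- ifelse(bonds$a1[rows] == a, bonds$a2[rows], bonds$a1[rows])
    elems <- atoms$element[nbrs]
    n_f <- sum(elems == "F")
    n_h <- sum(elems == "H") + atoms$implicit_h[a]
    n_hal <- sum(elems %in% c("Cl", "Br", "I"))
    if (n_f >= 2L && n_h == 0L && n_hal == 0L) return(TRUE)
  }
  FALSE
}

# Probe corpus for overlap analysis: the fixture compounds plus a few
# structures chosen so every non-redundant v4 pattern has a record only it
# captures (1,1,2,2-tetrafluoroethane for S1, 1,1,1,2-tetrafluoroethane for
# S5, perfluorodimethyl ether for S7).
probe_corpus <- function() {
  corp <- paper_corpus()[, c("name", "smiles")]
  dplyr::bind_rows(
    corp,
    tibble::tibble(
      name = c("1,1,2,2-tetrafluoroethane", "1,1,1,2-tetrafluoroethane",
               "perfluorodimethyl ether"),
      smiles = c("FC(F)C(F)F", "FCC(F)(F)F", "FC(F)(F)OC(F)(F)F")
    )
  )
}

# A V2000 molblock for trifluoromethane (CHF3) with one explicit hydrogen.
CHF3_MOLBLOCK <- paste(
  "trifluoromethane",
  "  pfasdef",
  "",
  "  4  3  0  0  0  0  0  0  0  0999 V2000",
  "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    1.0000    0.0000    0.0000 F   0  0  0  0  0  0  0  0  0  0  0  0",
  "   -1.0000    0.0000    0.0000 F   0  0  0  0  0  0  0  0  0  0  0  0",
  "    0.0000    1.0000    0.0000 F   0  0  0  0  0  0  0  0  0  0  0  0",
  "  1  2  1  0",
  "  1  3  1  0",
  "  1  4  1  0",
  "M  END",
  sep = "\n"
)

# Sodium fluoride as a charged two-atom molblock using an M  CHG line.
NAF_MOLBLOCK <- paste(
  "sodium fluoride",
  "  pfasdef",
  "",
  "  2  0  0  0  0  0  0  0  0  0999 V2000",
  "    0.0000    0.0000    0.0000 Na  0  0  0  0  0  0  0  0  0  0  0  0",
  "    2.0000    0.0000    0.0000 F   0  0  0  0  0  0  0  0  0  0  0  0",
  "M  CHG  2   1   1   2  -1",
  "M  END",
  sep = "\n"
)
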