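# SMILES reader.
#
# Supports the constitution-level language the PFAS rules need: organic-subset
# and bracket atoms (isotope, charge, explicit H count), single/double/triple/
# aromatic bonds, branches, ring closures (including %nn), and dot-separated
# components. Stereo marks (/ \ @) are accepted and ignored — every rule here
# is constitution-only. Radicals are perceived from bracket-atom valence
# deficits, the standard SMILES reading of e.g. [C](F)(F)F.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_SUBSET <- c("b", "c", "n", "o", "p", "s")

smiles_tokenize_error <- function(smiles, pos, what) {
  stop("SMILES parse error at position ", pos, " ('",
       substr(smiles, pos, min(nchar(smiles), pos + 5L)), "'): ", what,
       call. = FALSE)
}

parse_smiles_graph <- function(smiles) {
  n <- nchar(smiles)
  atoms <- list()      # each: list(element, aromatic, isotope, charge, h_explicit)
  bonds <- list()      # each: list(a1, a2, order, aromatic)
  prev <- NA_integer_  # index of previous atom for next bond
  stack <- integer(0)
  pending_bond <- NULL # "-" "=" "#" ":" or NULL (default)
  ring <- list()       # closure digit -> list(atom, bond)

  add_atom <- function(element, aromatic, isotope = NA_integer_,
                       charge = 0L, h_explicit = NA_integer_) {
    atoms[[length(atoms) + 1L]] <<- list(
      element = element, aromatic = aromatic, isotope = isotope,
      charge = charge, h_explicit = h_explicit
    )
    length(atoms)
  }
  add_bond <- function(a1, a2, sym) {
    aromatic_pair <- atoms[[a1]]$aromatic && atoms[[a2]]$aromatic
    if (is.null(sym)) {
      order <- if (aromatic_pair) 1.5 else 1
      arom <- aromatic_pair
    } else {
      order <- switch(sym, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5,
                      "/" = 1, "\\" = 1)
      arom <- identical(sym, ":")
    }
    bonds[[length(bonds) + 1L]] <<- list(a1 = a1, a2 = a2, order = order,
                                         aromatic = arom)
  }
  connect <- function(idx) {
    force(idx) # the atom must exist before add_bond inspects it
    if (!is.na(prev)) add_bond(prev, idx, pending_bond)
    pending_bond <<- NULL
    prev <<- idx
  }

  pos <- 1L
  while (pos <= n) {
    ch <- substr(smiles, pos, pos)
    two <- substr(smiles, pos, pos + 1L)
    if (ch == "[") {
      close <- regexpr("]", substr(smiles, pos, n), fixed = TRUE)
      if (close < 0L) smiles_tokenize_error(smiles, pos, "unclosed bracket atom")
      body <- substr(smiles, pos + 1L, pos + close - 2L)
      m <- regexec(
        "^([0-9]*)([A-Z][a-z]?|[a-z]|\\*)(@{1,2}|@TH[12])?(H[0-9]*)?([+-][0-9]*|\\++|-+)?(:[0-9]+)?$",
        body
      )
      parts <- regmatches(body, m)[[1]]
      if (length(parts) == 0L) {
        smiles_tokenize_error(smiles, pos, "malformed bracket atom")
      }
      iso <- if (nzchar(parts[2])) as.integer(parts[2]) else NA_integer_
      sym_raw <- parts[3]
      aromatic <- sym_raw %in% .AROMATIC_SUBSET
      element <- if (aromatic) {
        paste0(toupper(substr(sym_raw, 1, 1)), substr(sym_raw, 2, 10))
      } else sym_raw
      if (element == "*") {
        smiles_tokenize_error(smiles, pos, "wildcard atoms are not supported")
      }
      if (!is_known_element(element)) {
        smiles_tokenize_error(smiles, pos,
                              paste0("unknown element '", element, "'"))
      }
      hpart <- parts[5]
      h_explicit <- if (nzchar(hpart)) {
        if (hpart == "H") 1L else as.integer(substr(hpart, 2L, nchar(hpart)))
      } else 0L
      cpart <- parts[6]
      charge <- 0L
      if (nzchar(cpart)) {
        sign <- if (substr(cpart, 1, 1) == "+") 1L else -1L
        digits <- gsub("[+-]", "", cpart)
        charge <- if (nzchar(digits)) sign * as.integer(digits)
                  else sign * nchar(cpart)
      }
      idx <- add_atom(element, aromatic, iso, charge, h_explicit)
      connect(idx)
      pos <- pos + close
    } else if (two %in% c("Cl", "Br")) {
      connect(add_atom(two, FALSE))
      pos <- pos + 2L
    } else if (ch %in% .ORGANIC_SUBSET) {
      connect(add_atom(ch, FALSE))
      pos <- pos + 1L
    } else if (ch %in% .AROMATIC_SUBSET) {
      element <- toupper(ch)
      connect(add_atom(element, TRUE))
      pos <- pos + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- ch
      pos <- pos + 1L
    } else if (ch == "(") {
      if (is.na(prev)) smiles_tokenize_error(smiles, pos, "branch before any atom")
      stack <- c(stack, prev)
      pos <- pos + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) smiles_tokenize_error(smiles, pos, "unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pos <- pos + 1L
    } else if (grepl("^[0-9]$", ch) || ch == "%") {
      if (ch == "%") {
        key <- substr(smiles, pos + 1L, pos + 2L)
        if (!grepl("^[0-9]{2}$", key)) {
          smiles_tokenize_error(smiles, pos, "'%' must be followed by two digits")
        }
        pos <- pos + 3L
      } else {
        key <- ch
        pos <- pos + 1L
      }
      if (is.na(prev)) smiles_tokenize_error(smiles, pos, "ring bond before any atom")
      if (!is.null(ring[[key]])) {
        open <- ring[[key]]
        sym <- if (!is.null(pending_bond)) pending_bond else open$bond
        if (open$atom == prev) {
          smiles_tokenize_error(smiles, pos, "ring bond to the same atom")
        }
        add_bond(open$atom, prev, sym)
        ring[[key]] <- NULL
        pending_bond <- NULL
      } else {
        ring[[key]] <- list(atom = prev, bond = pending_bond)
        pending_bond <- NULL
      }
    } else if (ch == ".") {
      prev <- NA_integer_
      pending_bond <- NULL
      pos <- pos + 1L
    } else if (ch %in% c(" ", "\t")) {
      break # trailing title/whitespace: stop structure parsing
    } else {
      smiles_tokenize_error(smiles, pos, "unexpected character")
    }
  }
  if (length(ring) > 0L) {
    stop("SMILES parse error: unclosed ring bond(s) ",
         paste(names(ring), collapse = ", "), call. = FALSE)
  }
  if (length(stack) > 0L) {
    stop("SMILES parse error: unclosed branch", call. = FALSE)
  }
  if (length(atoms) == 0L) {
    stop("SMILES parse error: no atoms", call. = FALSE)
  }
  finish_graph(atoms, bonds)
}

# Shared finishing step for SMILES and molblock input: implicit hydrogens,
# radical perception, component assignment, per-component formulas.
finish_graph <- function(atoms, bonds, radical_override = NULL) {
  natoms <- length(atoms)
  atom_tbl <- tibble::tibble(
    atom = seq_len(natoms),
    element = vapply(atoms, `[[`, character(1), "element"),
    aromatic = vapply(atoms, `[[`, logical(1), "aromatic"),
    isotope = vapply(atoms, `[[`, integer(1), "isotope"),
    charge = vapply(atoms, `[[`, integer(1), "charge"),
    h_explicit = vapply(atoms, `[[`, integer(1), "h_explicit")
  )
  if (length(bonds) > 0L) {
    bond_tbl <- tibble::tibble(
      a1 = vapply(bonds, `[[`, numeric(1), "a1"),
      a2 = vapply(bonds, `[[`, numeric(1), "a2"),
      order = vapply(bonds, `[[`, numeric(1), "order"),
      aromatic = vapply(bonds, `[[`, logical(1), "aromatic")
    )
    bond_tbl$a1 <- as.integer(bond_tbl$a1)
    bond_tbl$a2 <- as.integer(bond_tbl$a2)
  } else {
    bond_tbl <- tibble::tibble(a1 = integer(0), a2 = integer(0),
                               order = numeric(0), aromatic = logical(0))
  }
  # aromatic atoms can be implied by aromatic bonds (molblock type-4 bonds)
  if (any(bond_tbl$aromatic)) {
    arom_atoms <- unique(c(bond_tbl$a1[bond_tbl$aromatic],
                           bond_tbl$a2[bond_tbl$aromatic]))
    atom_tbl$aromatic[arom_atoms] <- TRUE
  }

  bondsum <- numeric(natoms)
  degree <- integer(natoms)
  for (k in seq_len(nrow(bond_tbl))) {
    a1 <- bond_tbl$a1[k]; a2 <- bond_tbl$a2[k]; o <- bond_tbl$order[k]
    bondsum[a1] <- bondsum[a1] + o
    bondsum[a2] <- bondsum[a2] + o
    degree[a1] <- degree[a1] + 1L
    degree[a2] <- degree[a2] + 1L
  }
  bondsum_i <- as.integer(ceiling(bondsum - 1e-9))

  implicit_h <- integer(natoms)
  radical <- integer(natoms)
  for (i in seq_len(natoms)) {
    allowed <- .VALENCES[[atom_tbl$element[i]]]
    if (is.na(atom_tbl$h_explicit[i])) {
      # organic-subset atom: fill valence with implicit hydrogens
      if (!is.null(allowed)) {
        fits <- allowed[allowed >= bondsum_i[i]]
        implicit_h[i] <- if (length(fits)) min(fits) - bondsum_i[i] else 0L
      }
    } else {
      implicit_h[i] <- atom_tbl$h_explicit[i]
      # bracket atom: valence deficit (after charge) = unpaired electrons
      if (!is.null(allowed)) {
        eff <- bondsum_i[i] + implicit_h[i] + abs(atom_tbl$charge[i])
        if (eff > 0L || atom_tbl$charge[i] == 0L) {
          fits <- allowed[allowed >= eff]
          radical[i] <- if (length(fits)) min(fits) - eff else 0L
        }
      }
    }
  }
  if (!is.null(radical_override)) radical <- radical_override
  atom_tbl$implicit_h <- implicit_h
  atom_tbl$radical <- radical
  atom_tbl$degree <- degree
  atom_tbl$bond_order_sum <- bondsum

  # connected components
  g <- igraph::graph_from_data_frame(
    bond_tbl[, c("a1", "a2")],
    directed = FALSE,
    vertices = data.frame(name = seq_len(natoms))
  )
  atom_tbl$component <- as.integer(
    igraph::components(g)$membership[as.character(seq_len(natoms))]
  )
  list(atoms = atom_tbl, bonds = bond_tbl)
}

graph_formula <- function(atom_tbl, which_atoms = NULL) {
  sub <- if (is.null(which_atoms)) atom_tbl
         else atom_tbl[atom_tbl$atom %in% which_atoms, ]
  counts <- tapply(rep(1L, nrow(sub)), sub$element, sum)
  h <- sum(sub$implicit_h)
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (h > 0L) {
    counts["H"] <- (if ("H" %in% names(counts)) counts[["H"]] else 0L) + h
  }
  new_mol_formula(counts)
}
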