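# SDF / MDL V2000 molblock reader.
#
# Reads the connection table (atom and bond blocks) plus the property lines
# that matter for classification: M  CHG (formal charges), M  RAD (radicals),
# M  ISO (isotope labels). Per the V2000 format, a CHG/RAD/ISO property line
# supersedes the legacy atom-block charge column. Implicit hydrogens are
# assigned from the usual valence model (honouring an explicit valence field
# when present), so a molblock without explicit hydrogens and the equivalent
# SMILES profile identically.

parse_molblock <- function(text) {
  lines <- strsplit(text, "\r?\n")[[1]]
  if (length(lines) < 4L) stop("molblock too short", call. = FALSE)
  counts_line <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts_line, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts_line, 4, 6)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 1L) {
    stop("invalid counts line in molblock", call. = FALSE)
  }
  if (length(lines) < 4L + natoms + nbonds) {
    stop("molblock truncated: counts line promises ", natoms, " atoms and ",
         nbonds, " bonds", call. = FALSE)
  }

  legacy_charge <- function(code) {
    # atom-block charge codes: 1..7 = +3 +2 +1 (4 = radical) -1 -2 -3
    switch(as.character(code),
           "1" = 3L, "2" = 2L, "3" = 1L, "5" = -1L, "6" = -2L, "7" = -3L, 0L)
  }

  atoms <- vector("list", natoms)
  valence_field <- integer(natoms)
  legacy_rad <- logical(natoms)
  for (i in seq_len(natoms)) {
    ln <- lines[4L + i]
    element <- trimws(substr(ln, 32, 34))
    if (!is_known_element(element)) {
      stop("unknown element '", element, "' in molblock atom ", i,
           call. = FALSE)
    }
    code <- suppressWarnings(as.integer(substr(ln, 37, 39)))
    if (is.na(code)) code <- 0L
    legacy_rad[i] <- code == 4L
    val <- suppressWarnings(as.integer(substr(ln, 49, 51)))
    valence_field[i] <- if (is.na(val)) 0L else val
    atoms[[i]] <- list(element = element, aromatic = FALSE,
                       isotope = NA_integer_, charge = legacy_charge(code),
                       h_explicit = NA_integer_)
  }

  bonds <- vector("list", nbonds)
  if (nbonds > 0L) {
    for (k in seq_len(nbonds)) {
      ln <- lines[4L + natoms + k]
      a1 <- as.integer(substr(ln, 1, 3))
      a2 <- as.integer(substr(ln, 4, 6))
      type <- as.integer(substr(ln, 7, 9))
      if (is.na(a1) || is.na(a2) || a1 < 1L || a2 < 1L ||
          a1 > natoms || a2 > natoms) {
        stop("invalid bond line ", k, " in molblock", call. = FALSE)
      }
      order <- switch(as.character(type), "1" = 1, "2" = 2, "3" = 3,
                      "4" = 1.5, 1)
      bonds[[k]] <- list(a1 = a1, a2 = a2, order = order,
                         aromatic = identical(order, 1.5))
    }
  }

  # property block
  prop_lines <- lines[-seq_len(4L + natoms + nbonds)]
  radical_override <- NULL
  seen_chg <- FALSE
  parse_pairs <- function(ln) {
    body <- trimws(substr(ln, 7, nchar(ln)))
    nums <- as.integer(strsplit(body, "\\s+")[[1]])
    cnt <- nums[1]
    matrix(nums[1 + seq_len(2L * cnt)], ncol = 2L, byrow = TRUE)
  }
  rad <- integer(natoms)
  for (ln in prop_lines) {
    tag <- substr(ln, 1, 6)
    if (tag == "M  CHG") {
      if (!seen_chg) { # first CHG line supersedes all legacy charges
        for (i in seq_len(natoms)) atoms[[i]]$charge <- 0L
        seen_chg <- TRUE
      }
      for (r in seq_len(nrow(parse_pairs(ln)))) {
        p <- parse_pairs(ln)[r, ]
        atoms[[p[1]]]$charge <- p[2]
      }
    } else if (tag == "M  RAD") {
      for (r in seq_len(nrow(parse_pairs(ln)))) {
        p <- parse_pairs(ln)[r, ]
        # RAD values: 1 singlet, 2 doublet, 3 triplet -> unpaired electrons
        rad[p[1]] <- switch(as.character(p[2]), "2" = 1L, "3" = 2L, 0L)
      }
      radical_override <- rad
    } else if (tag == "M  ISO") {
      for (r in seq_len(nrow(parse_pairs(ln)))) {
        p <- parse_pairs(ln)[r, ]
        atoms[[p[1]]]$isotope <- p[2]
      }
    } else if (tag == "M  END") {
      break
    }
  }
  if (is.null(radical_override) && any(legacy_rad)) {
    radical_override <- as.integer(legacy_rad)
  }

  # implicit hydrogens in molblocks follow the valence model for every atom;
  # mark all atoms as "organic-subset-like" (h_explicit NA), then honour an
  # explicit valence field (15 encodes zero valence).
  g <- finish_graph(atoms, bonds, radical_override = radical_override)
  at <- g$atoms
  for (i in seq_len(natoms)) {
    vf <- valence_field[i]
    if (vf > 0L) {
      target <- if (vf == 15L) 0L else vf
      at$implicit_h[i] <-
        max(0L, target - as.integer(ceiling(at$bond_order_sum[i] - 1e-9)))
    } else if (at$charge[i] != 0L && at$element[i] %in% names(.VALENCES)) {
      # charged atoms: shrink/grow the valence target by |charge| so that a
      # carboxylate oxygen ([O-], one bond) gets no implicit hydrogen
      allowed <- .VALENCES[[at$element[i]]]
      bs <- as.integer(ceiling(at$bond_order_sum[i] - 1e-9))
      eff <- bs + abs(at$charge[i])
      fits <- allowed[allowed >= eff]
      at$implicit_h[i] <- if (length(fits)) min(fits) - eff else 0L
    }
  }
  list(atoms = at, bonds = g$bonds)
}
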